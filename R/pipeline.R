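#' Default pipeline configuration
#'
#' All analysis constants in one structured list, with the conventional
#' values used throughout the package: 1-30 Hz band-pass and 48-52 Hz
#' notch; epochs from 500 ms before to 1000 ms after the stimulus; the
#' consistency test window opening 200 ms prestimulus; 5000 randomization
#' iterations; 100 split-half cross-validation iterations; the 5%
#' run-length rule; the 9/30 clinical threshold; alpha 0.05 per timepoint
#' and 0.025 per tail for the surrogate comparisons. Stage seeds are
#' derived deterministically from the single master `seed`.
#'
#' @return Nested named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = NULL,                      # master seed: must be set by the user
    cohorts = c("preterm", "term"),
    simulate = list(
      n_subjects_per_group = 20, n_channels = 18, fs_hz = 500,
      epoch_window_ms = c(-500, 1000), snr = 5, n_templates = 4,
      jitter_sd_ms = 10, onset_shift_ms = 0,
      facial_p = c(0.8, 0.1), obstruction_bout_rate = 0.3
    ),
    filters = list(band_hz = c(1, 30), notch_hz = c(48, 52),
                   apply_to_epochs = FALSE),
    nfcs = list(constellation = "nfcs_p3", threshold = 9,
                min_coverage = 0.6),
    windows = list(tct_ms = c(-200, 1000), postlance_ms = c(0, 1000)),
    randomization = list(n_iter = 5000, alpha = 0.05, min_run_frac = 0.05),
    cv = list(n_iter = 100, k_range = 2:12, split = 0.5,
              gain_threshold = 0.01),
    activation = list(n_iter = 5000, alpha = 0.05),
    surrogate = list(n_iter = 5000, alpha_two_tailed = 0.05,
                     act_draws = 500, match_window_ms = 200)
  )
}

#' Validate a pipeline configuration
#'
#' Fills defaults from [default_config()], rejects unknown keys, and
#' type-checks every field with a path-to-field error message. A master
#' seed is mandatory: every stochastic stage derives its own seed from it.
#'
#' @param config Named list of overrides, or a path to a YAML/JSON file.
#' @return The complete validated configuration (class `run_config`).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- read_config_file(config)
  }
  if (!is.list(config)) abort("config must be a named list or a file path")
  defaults <- default_config()
  check_keys(config, defaults, path = "config")
  cfg <- modifyList(defaults, config)
  if (is.null(cfg$seed)) abort("config$seed: a master seed is required")
  check_int(cfg$seed, "config$seed", min = 0)
  check_window(cfg$simulate$epoch_window_ms, "config$simulate$epoch_window_ms")
  check_window(cfg$windows$tct_ms, "config$windows$tct_ms")
  check_window(cfg$windows$postlance_ms, "config$windows$postlance_ms")
  for (f in c("n_subjects_per_group", "n_channels", "n_templates")) {
    check_int(cfg$simulate[[f]], paste0("config$simulate$", f), min = 1)
  }
  if (!(cfg$simulate$fs_hz > 0)) abort("config$simulate$fs_hz: must be positive")
  if (!(cfg$simulate$snr > 0)) abort("config$simulate$snr: must be positive")
  check_int(cfg$randomization$n_iter, "config$randomization$n_iter", min = 1)
  check_int(cfg$cv$n_iter, "config$cv$n_iter", min = 1)
  check_int(cfg$activation$n_iter, "config$activation$n_iter", min = 1)
  check_int(cfg$surrogate$n_iter, "config$surrogate$n_iter", min = 1)
  for (a in c(cfg$randomization$alpha, cfg$activation$alpha,
              cfg$surrogate$alpha_two_tailed)) {
    if (!(a > 0 && a < 1)) abort("alpha values must lie in (0, 1)")
  }
  if (!cfg$nfcs$constellation %in% c("nfcs_p3", "nfcs3", "nfcs7")) {
    abort("config$nfcs$constellation: unknown constellation")
  }
  structure(cfg, class = c("run_config", "list"))
}

read_config_file <- function(path) {
  if (!file.exists(path)) abort(paste("config file not found:", path))
  if (grepl("\\.ya?ml$", path) &&
      requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

check_keys <- function(x, ref, path) {
  unknown <- setdiff(names(x), names(ref))
  if (length(unknown)) {
    abort(paste0(path, ": unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  for (k in names(x)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) && is.list(x[[k]])) {
      check_keys(x[[k]], ref[[k]], paste0(path, "$", k))
    }
  }
}

check_int <- function(x, path, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != round(x)) {
    abort(paste0(path, ": must be a single integer"))
  }
  if (x < min) abort(paste0(path, ": must be >= ", min))
}

check_window <- function(w, path) {
  if (!is.numeric(w) || length(w) != 2) {
    abort(paste0(path, ": must be a numeric (start, end) pair"))
  }
  if (w[2] <= w[1]) abort(paste0(path, ": window end must exceed start"))
}

# deterministic stage seed below 2^31, derived from the master seed
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483647)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes, per cohort: synthetic cohort generation (EEG epochs and facial
#' coding), NFCS scoring with missing-data handling and clinical-threshold
#' grouping, common-average referencing, the topographic consistency test
#' per clinical group, the topographic ANOVA between groups, microstate
#' identification (split-half cross-validated k, final clustering),
#' back-fitting with baseline-null activation testing, event extraction,
#' and the surrogate-null comparison of microstate parameters. Every
#' stage's outputs are written (CSV/JSON) before the next begins, so a
#' failure leaves completed outputs intact.
#'
#' @param config A validated configuration ([validate_config()]) or a list
#'   of overrides.
#' @param out_dir Output directory.
#' @return A `run_record`: tibble of stages with timings and output-file
#'   MD5 digests, plus the config hash.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  record <- list()
  note <- function(stage, cohort, files, elapsed) {
    record[[length(record) + 1]] <<- tibble::tibble(
      stage = stage, cohort = cohort, file = basename(files),
      md5 = unname(tools::md5sum(files)), seconds = elapsed)
  }
  run_stage <- function(stage, cohort, fun) {
    t0 <- proc.time()[["elapsed"]]
    files <- tryCatch(fun(), error = function(e) {
      abort(sprintf("stage '%s' (%s) failed: %s", stage, cohort,
                    conditionMessage(e)))
    })
    note(stage, cohort, files, proc.time()[["elapsed"]] - t0)
  }
  for (cohort in cfg$cohorts) {
    cdir <- file.path(out_dir, cohort)
    dir.create(cdir, showWarnings = FALSE, recursive = TRUE)
    seed0 <- derive_seed(cfg$seed, cohort)
    env <- new.env()
    run_stage("simulate", cohort, function() {
      sim <- cfg$simulate
      with_seed(derive_seed(seed0, "templates"), {
        tm <- make_templates(sim$n_templates, sim$n_channels)
      })
      entries <- script_timetable(sim$n_templates, sim$epoch_window_ms)
      script1 <- microstate_script(entries, tm,
                                   jitter_sd_ms = sim$jitter_sd_ms,
                                   snr = sim$snr)
      entries2 <- entries
      if (sim$onset_shift_ms != 0) {
        entries2$onset_ms[nrow(entries2)] <-
          entries2$onset_ms[nrow(entries2)] + sim$onset_shift_ms
      }
      script2 <- microstate_script(entries2, tm,
                                   jitter_sd_ms = sim$jitter_sd_ms,
                                   snr = sim$snr)
      spec <- cohort_spec(sim$n_subjects_per_group, list(script1, script2),
                          n_channels = sim$n_channels, fs_hz = sim$fs_hz,
                          epoch_window_ms = sim$epoch_window_ms,
                          seed = derive_seed(seed0, "erp"))
      env$erp <- generate_erp_cohort(spec)
      env$facial <- generate_facial_cohort(facial_sim_spec(
        sim$n_subjects_per_group, sim$facial_p,
        obstruction = list(bout_rate = sim$obstruction_bout_rate,
                           bout_length_mean = 2),
        seed = derive_seed(seed0, "facial")))
      f1 <- file.path(cdir, "cohort_manifest.json")
      write_cohort_manifest(env$erp, f1)
      f2 <- file.path(cdir, "facial_coding.tsv")
      write_facial_coding(env$facial$coding, f2)
      c(f1, f2)
    })
    run_stage("score_nfcs", cohort, function() {
      scores <- score_nfcs(env$facial$coding, cfg$nfcs$constellation,
                           cfg$nfcs$min_coverage)
      react <- dplyr::filter(scores, .data$epoch == "reactivity")
      env$groups_tbl <- classify_clinical(react, cfg$nfcs$threshold)
      f <- file.path(cdir, "nfcs_scores.csv")
      utils::write.csv(env$groups_tbl, f, row.names = FALSE)
      f
    })
    run_stage("preprocess", cohort, function() {
      all_es <- bind_epoch_sets(env$erp$epochs)
      if (isTRUE(cfg$filters$apply_to_epochs)) {
        d <- all_es$data
        for (s in seq_len(dim(d)[1])) {
          d[s, , ] <- bandpass_notch(d[s, , ], all_es$fs_hz,
                                     cfg$filters$band_hz,
                                     cfg$filters$notch_hz)
        }
        all_es <- epoch_set(d, all_es$fs_hz, all_es$times_ms,
                            all_es$montage, "original",
                            all_es$subject_ids)
      }
      all_es <- rereference_common_average(all_es)
      grp <- env$groups_tbl
      clin <- grp$subject_id[!is.na(grp$clinical_group) &
                               grp$clinical_group == "NFCS-clinical"]
      sub <- grp$subject_id[!is.na(grp$clinical_group) &
                              grp$clinical_group == "NFCS-subclinical"]
      if (length(clin) < 2 || length(sub) < 2) {
        abort("need at least 2 subjects per clinical group")
      }
      env$by_group <- list(
        subclinical = subset_epochs(all_es, sub),
        clinical = subset_epochs(all_es, clin))
      f <- file.path(cdir, "clinical_groups.csv")
      utils::write.csv(
        data.frame(subject_id = c(sub, clin),
                   clinical_group = rep(c("NFCS-subclinical",
                                          "NFCS-clinical"),
                                        c(length(sub), length(clin)))),
        f, row.names = FALSE)
      f
    })
    run_stage("tct", cohort, function() {
      env$tct <- lapply(seq_along(env$by_group), function(i) {
        tct(env$by_group[[i]], cfg$windows$tct_ms,
            n_iter = cfg$randomization$n_iter,
            alpha = cfg$randomization$alpha,
            seed = derive_seed(seed0, paste0("tct", i)),
            min_run_frac = cfg$randomization$min_run_frac)
      })
      names(env$tct) <- names(env$by_group)
      f <- file.path(cdir, "tct.csv")
      utils::write.csv(
        dplyr::bind_rows(lapply(names(env$tct), function(g) {
          dplyr::mutate(tidy(env$tct[[g]]), group = g)
        })), f, row.names = FALSE)
      f
    })
    run_stage("tanova", cohort, function() {
      res <- tanova(env$by_group[[1]], env$by_group[[2]],
                    n_iter = cfg$randomization$n_iter,
                    alpha = cfg$randomization$alpha,
                    seed = derive_seed(seed0, "tanova"),
                    min_run_frac = cfg$randomization$min_run_frac)
      f <- file.path(cdir, "tanova.csv")
      utils::write.csv(tidy(res), f, row.names = FALSE)
      f
    })
    run_stage("microstates", cohort, function() {
      sel <- select_k(env$by_group, env$tct,
                      k_range = cfg$cv$k_range, n_iter = cfg$cv$n_iter,
                      split = cfg$cv$split,
                      seed = derive_seed(seed0, "cv"),
                      gain_threshold = cfg$cv$gain_threshold)
      pool <- pool_consistent_maps(env$by_group, env$tct)
      env$set <- cluster_microstates(pool, sel$k_star)
      f1 <- file.path(cdir, "cv_curve.csv")
      utils::write.csv(sel$curve, f1, row.names = FALSE)
      f2 <- file.path(cdir, "microstate_templates.csv")
      utils::write.csv(tidy(env$set), f2, row.names = FALSE)
      f3 <- file.path(cdir, "microstates_meta.json")
      jsonlite::write_json(list(k_star = sel$k_star,
                                n_maps = nrow(pool$maps),
                                seed = derive_seed(seed0, "cv")),
                           f3, auto_unbox = TRUE, digits = NA)
      c(f1, f2, f3)
    })
    run_stage("events", cohort, function() {
      bp <- baseline_map_pool(env$by_group,
                              c(cfg$simulate$epoch_window_ms[1], 0))
      env$series <- lapply(seq_along(env$by_group), function(i) {
        s <- fit_microstates(env$by_group[[i]], env$set)
        activation_significance(
          s, env$by_group[[i]], bp, alpha = cfg$activation$alpha,
          n_iter = cfg$activation$n_iter,
          seed = derive_seed(seed0, paste0("act", i)),
          postlance_ms = diff(cfg$windows$postlance_ms))
      })
      names(env$series) <- names(env$by_group)
      md <- pooled_mean_durations(env$series)
      env$events <- lapply(env$series, extract_events, mean_durations = md)
      f <- file.path(cdir, "microstate_events.csv")
      utils::write.csv(
        dplyr::bind_rows(lapply(names(env$events), function(g) {
          dplyr::mutate(env$events[[g]], group = g)
        })), f, row.names = FALSE)
      f
    })
    run_stage("compare", cohort, function() {
      bp <- baseline_map_pool(env$by_group,
                              c(cfg$simulate$epoch_window_ms[1], 0))
      cmp <- surrogate_compare(
        env$by_group[[1]], env$by_group[[2]], env$set, bp,
        n_iter = cfg$surrogate$n_iter,
        seed = derive_seed(seed0, "surrogate"),
        alpha_two_tailed = cfg$surrogate$alpha_two_tailed,
        act_draws = cfg$surrogate$act_draws,
        min_run_ms = 0.05 * diff(cfg$windows$postlance_ms),
        match_window_ms = cfg$surrogate$match_window_ms)
      f1 <- file.path(cdir, "parameter_comparison.csv")
      utils::write.csv(cmp$differences, f1, row.names = FALSE)
      f2 <- file.path(cdir, "comparison_meta.json")
      jsonlite::write_json(list(n_iter = cmp$n_iter, seed = cmp$seed,
                                alpha_two_tailed = cmp$alpha_two_tailed),
                           f2, auto_unbox = TRUE, digits = NA)
      c(f1, f2)
    })
  }
  structure(list(config_hash = unname(tools::md5sum(cfg_path)),
                 stages = dplyr::bind_rows(record)),
            class = "run_record")
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record> config %s\n", x$config_hash))
  s <- dplyr::distinct(x$stages, .data$stage, .data$cohort, .data$seconds)
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %-8s %6.1f s\n", s$stage[i], s$cohort[i],
                s$seconds[i]))
  }
  invisible(x)
}

# default scripted timetable for n templates spread over the postlance
# second (used by the pipeline's synthetic stage)
script_timetable <- function(n_templates, epoch_window_ms) {
  onsets <- seq(50, 650, length.out = n_templates)
  durs <- rep(150, n_templates)
  tibble::tibble(template_id = paste0("M", seq_len(n_templates)),
                 onset_ms = onsets, duration_ms = durs,
                 amplitude_uv = 4)
}

# stack the subjects of several epoch_sets sharing a grid
bind_epoch_sets <- function(sets) {
  sets <- unname(sets)
  for (i in seq_along(sets)[-1]) check_same_grid(sets[[1]], sets[[i]])
  d <- do.call(abind_first, lapply(sets, function(s) s$data))
  epoch_set(d, sets[[1]]$fs_hz, sets[[1]]$times_ms, sets[[1]]$montage,
            sets[[1]]$reference,
            subject_ids = unlist(lapply(sets, function(s) s$subject_ids)))
}

abind_first <- function(...) {
  mats <- list(...)
  ns <- vapply(mats, function(m) dim(m)[1], 0L)
  out <- array(0, c(sum(ns), dim(mats[[1]])[2], dim(mats[[1]])[3]))
  at <- 0
  for (m in mats) {
    out[at + seq_len(dim(m)[1]), , ] <- m
    at <- at + dim(m)[1]
  }
  out
}

subset_epochs <- function(es, subject_ids) {
  idx <- match(subject_ids, es$subject_ids)
  if (anyNA(idx)) abort("unknown subject id")
  epoch_set(es$data[idx, , , drop = FALSE], es$fs_hz, es$times_ms,
            es$montage, es$reference, subject_ids = es$subject_ids[idx])
}
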