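#' Build a ground-truth microstate script
#'
#' A microstate script is the generative ground truth for one synthetic
#' group: a set of average-referenced, unit-GFP template topographies and a
#' timetable of engagements (which template, when, for how long, how
#' strongly). Scripted events are rendered as boxcars with half-cosine
#' on/off ramps, jittered across subjects, and embedded in noise by
#' [generate_erp_cohort()].
#'
#' @param entries Data frame with columns `template_id`, `onset_ms`,
#'   `duration_ms` (> 0) and `amplitude_uv` (>= 0); sorted by onset on
#'   construction.
#' @param templates Matrix (templates x channels, rownames = template ids)
#'   or named list of channel vectors. Each template must be
#'   average-referenced with unit GFP (tolerance 1e-9); see
#'   [make_templates()].
#' @param jitter_sd_ms Gaussian SD of the across-subject onset jitter (ms);
#'   realized onsets are truncated so every event stays inside the epoch.
#' @param snr Requested epoch-wise signal-to-noise ratio (signal power over
#'   noise power); `Inf` gives noise-free epochs.
#' @param ramp_ms Width of each half-cosine edge of the event envelope (ms).
#' @return An object of class `microstate_script`.
#' @export
microstate_script <- function(entries, templates, jitter_sd_ms = 10,
                              snr = 5, ramp_ms = 10) {
  entries <- tibble::as_tibble(entries)
  need <- c("template_id", "onset_ms", "duration_ms", "amplitude_uv")
  if (!all(need %in% names(entries))) {
    abort(paste("entries needs columns:", paste(need, collapse = ", ")))
  }
  if (is.list(templates) && !is.matrix(templates)) {
    templates <- do.call(rbind, templates)
  }
  if (is.null(rownames(templates))) {
    rownames(templates) <- paste0("M", seq_len(nrow(templates)))
  }
  if (any(entries$duration_ms <= 0)) abort("durations must be positive")
  if (any(entries$amplitude_uv < 0)) abort("amplitudes must be non-negative")
  if (jitter_sd_ms < 0) abort("jitter_sd_ms must be non-negative")
  if (!(snr > 0)) abort("snr must be positive")
  if (!all(entries$template_id %in% rownames(templates))) {
    abort("entry references an unknown template id")
  }
  if (max(abs(rowMeans(templates))) > 1e-9) {
    abort("templates must be average-referenced (channel mean 0)")
  }
  g <- apply(templates, 1, gfp)
  if (max(abs(g - 1)) > 1e-9) abort("templates must have unit GFP")
  entries <- dplyr::arrange(entries, .data$onset_ms)
  structure(list(entries = entries, templates = templates,
                 jitter_sd_ms = jitter_sd_ms, snr = snr, ramp_ms = ramp_ms),
            class = "microstate_script")
}

#' Random average-referenced, unit-GFP template topographies
#'
#' Draws smooth random scalp maps, centers them to the average reference,
#' optionally orthogonalizes them (Gram-Schmidt), and normalizes each to
#' unit GFP. Orthogonal templates make planted-recovery tests unambiguous.
#'
#' @param k Number of templates.
#' @param n_channels Number of channels (>= k + 1 when `orthogonal`).
#' @param orthogonal Orthogonalize across templates (default TRUE).
#' @param ids Template ids; default `M1..Mk`.
#' @return k x n_channels matrix with template ids as rownames.
#' @export
make_templates <- function(k, n_channels = 18, orthogonal = TRUE,
                           ids = paste0("M", seq_len(k))) {
  if (orthogonal && k >= n_channels) {
    abort("need more channels than orthogonal templates")
  }
  tm <- matrix(rnorm(k * n_channels), k)
  tm <- tm - rowMeans(tm)
  if (orthogonal && k > 1) {
    for (i in 2:k) {
      for (j in 1:(i - 1)) {
        tm[i, ] <- tm[i, ] - sum(tm[i, ] * tm[j, ]) / sum(tm[j, ]^2) * tm[j, ]
      }
    }
  }
  tm <- tm / apply(tm, 1, gfp)
  rownames(tm) <- ids
  tm
}

#' Specify a synthetic ERP cohort
#'
#' @param n_subjects_per_group Integer >= 2.
#' @param group_scripts List of 2 [microstate_script()] objects (one per
#'   group) sharing a channel count.
#' @param n_channels Number of channels; must match the scripts.
#' @param fs_hz Sampling rate (default 500; 2000 is supported).
#' @param epoch_window_ms Epoch `(start, end)` in ms; must contain 0.
#' @param noise_model List with `pink_exponent` (spectral 1/f^alpha slope,
#'   default 1) and `spatial_smoothing` (Gaussian kernel width over
#'   electrode great-circle distance, radians, default 0.6).
#' @param montage Channel names (default [default_montage()]).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects_per_group, group_scripts,
                        n_channels = 18, fs_hz = 500,
                        epoch_window_ms = c(-500, 1000),
                        noise_model = list(pink_exponent = 1,
                                           spatial_smoothing = 0.6),
                        montage = default_montage(), seed = 1L) {
  if (n_subjects_per_group < 2) abort("need at least 2 subjects per group")
  if (n_channels < 4) abort("need at least 4 channels")
  if (!(fs_hz > 0)) abort("fs_hz must be positive")
  if (!(epoch_window_ms[1] <= 0 && epoch_window_ms[2] > 0)) {
    abort("epoch window must contain 0")
  }
  if (length(group_scripts) != 2 ||
      !all(vapply(group_scripts, inherits, TRUE, "microstate_script"))) {
    abort("group_scripts must be a list of 2 microstate_script objects")
  }
  nch <- vapply(group_scripts, function(s) ncol(s$templates), 0L)
  if (any(nch != n_channels)) {
    abort("scripts and spec disagree on channel count")
  }
  if (length(montage) != n_channels) {
    montage <- paste0("ch", seq_len(n_channels))
  }
  for (s in group_scripts) {
    bad <- s$entries$onset_ms < epoch_window_ms[1] |
      s$entries$onset_ms + s$entries$duration_ms > epoch_window_ms[2]
    if (any(bad)) abort("scripted event extends outside the epoch window")
  }
  structure(list(n_subjects_per_group = as.integer(n_subjects_per_group),
                 group_scripts = group_scripts, n_channels = n_channels,
                 fs_hz = fs_hz, epoch_window_ms = epoch_window_ms,
                 noise_model = noise_model, montage = montage,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a two-group synthetic ERP cohort with known ground truth
#'
#' Renders each group's microstate script into per-subject epochs: the
#' noise-free signal is the sum over scripted events of
#' `amplitude x template x envelope(onset + jitter, duration)` (boxcar with
#' half-cosine edges), to which spatially smoothed pink noise is added,
#' scaled per subject so that the epoch-wise signal-to-noise power ratio
#' equals the script's `snr`. All data are common-average referenced.
#'
#' @param spec A [cohort_spec()].
#' @return List with `epochs` (named list of two [epoch_set()]s, `group1`
#'   and `group2`), `ground_truth` (tibble of realized per-subject event
#'   onsets) and `spec`.
#' @export
generate_erp_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    times <- epoch_times(spec$epoch_window_ms, spec$fs_hz)
    K <- spatial_kernel(spec$montage, spec$noise_model$spatial_smoothing)
    out <- list()
    gt <- list()
    for (g in 1:2) {
      script <- spec$group_scripts[[g]]
      subs <- vector("list", spec$n_subjects_per_group)
      for (s in seq_len(spec$n_subjects_per_group)) {
        r <- render_subject(script, times, spec$epoch_window_ms)
        noise <- rereference_common_average(
          spatial_pink_noise(spec$n_channels, length(times), spec$fs_hz,
                             spec$noise_model$pink_exponent, K))
        ps <- mean(r$signal^2)          # templates are average-referenced
        pn <- mean(noise^2)
        scale <- if (ps > 0 && is.finite(script$snr)) {
          sqrt(ps / (script$snr * pn))
        } else if (ps > 0) 0 else 1 / sqrt(pn)
        subs[[s]] <- r$signal + scale * noise
        gt[[length(gt) + 1]] <- dplyr::mutate(
          r$realized, group = paste0("group", g),
          subject_id = sprintf("G%dS%02d", g, s), .before = 1)
      }
      out[[paste0("group", g)]] <- epoch_set(
        subs, spec$fs_hz, times, spec$montage, "common_average",
        subject_ids = sprintf("G%dS%02d", g,
                              seq_len(spec$n_subjects_per_group)))
    }
    list(epochs = out, ground_truth = dplyr::bind_rows(gt), spec = spec)
  })
}

epoch_times <- function(window_ms, fs_hz) {
  dt <- 1000 / fs_hz
  off0 <- round(window_ms[1] * fs_hz / 1000)
  n <- round((window_ms[2] - window_ms[1]) * fs_hz / 1000)
  (off0 + seq_len(n) - 1) * dt
}

# boxcar with half-cosine edges over the time axis (ms)
event_envelope <- function(times, onset, duration, ramp) {
  ramp <- min(ramp, duration / 2)
  e <- numeric(length(times))
  t1 <- onset
  t2 <- onset + duration
  inside <- times >= t1 & times < t2
  e[inside] <- 1
  if (ramp > 0) {
    up <- inside & times < t1 + ramp
    dn <- inside & times >= t2 - ramp
    e[up] <- 0.5 - 0.5 * cos(pi * (times[up] - t1) / ramp)
    e[dn] <- 0.5 - 0.5 * cos(pi * (t2 - times[dn]) / ramp)
  }
  e
}

# one subject's noise-free signal plus realized (jittered) onsets
render_subject <- function(script, times, window_ms) {
  nch <- ncol(script$templates)
  sig <- matrix(0, nch, length(times))
  realized <- script$entries
  for (i in seq_len(nrow(realized))) {
    en <- realized[i, ]
    j <- rnorm(1, 0, script$jitter_sd_ms)
    lo <- window_ms[1] - en$onset_ms
    hi <- window_ms[2] - en$onset_ms - en$duration_ms
    j <- min(max(j, lo), hi)          # truncate: event stays inside epoch
    onset <- en$onset_ms + j
    realized$onset_ms[i] <- onset
    env <- event_envelope(times, onset, en$duration_ms, script$ramp_ms)
    sig <- sig + en$amplitude_uv *
      script$templates[en$template_id, ] %o% env
  }
  list(signal = sig, realized = realized)
}

# Gaussian spatial mixing kernel over great-circle electrode distance
spatial_kernel <- function(montage, width) {
  pos <- tryCatch(montage_1020(montage), error = function(e) NULL)
  n <- length(montage)
  if (is.null(pos) || is.null(width) || width <= 0) return(diag(n))
  ang <- montage_angles(pos)
  K <- exp(-ang^2 / (2 * width^2))
  K / sqrt(rowSums(K^2))
}

# channels x time pink (1/f^alpha) noise, spatially mixed by K
spatial_pink_noise <- function(n_channels, n_samples, fs_hz, alpha, K) {
  w <- matrix(rnorm(n_samples * n_channels), n_samples, n_channels)
  f <- c(0, seq_len(n_samples - 1)) * fs_hz / n_samples
  f <- pmin(f, fs_hz - f)           # two-sided frequency magnitude
  scale <- c(0, f[-1]^(-alpha / 2))
  spec <- mvfft(w) * scale
  x <- Re(mvfft(spec, inverse = TRUE)) / n_samples
  x <- t(x)                         # channels x time
  x <- K %*% x
  x / sqrt(mean(x^2))
}

# evaluate code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
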