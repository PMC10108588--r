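#' Phase-randomized surrogate of one subject's epoch
#'
#' Multiplies the Fourier coefficients of every channel by a common random
#' phase sequence (conjugate-symmetric, so the result is real). Each
#' channel's amplitude spectrum is preserved exactly, and because the same
#' phases rotate every channel, the instantaneous cross-channel structure
#' (the set of topographies visited) is preserved too; what is destroyed
#' is the alignment of those topographies to the stimulus. Surrogate
#' cohorts therefore share all single-subject spectral and topographic
#' statistics with the originals but carry no stimulus-locked effect.
#'
#' @param mat Channels x time numeric matrix.
#' @return Surrogate matrix, same dimensions.
#' @export
phase_randomize <- function(mat) {
  n <- ncol(mat)
  rot <- rep(1 + 0i, n)
  m <- floor((n - 1) / 2)
  if (m >= 1) {
    phi <- runif(m, 0, 2 * pi)
    rot[2:(m + 1)] <- exp(1i * phi)
    rot[n:(n - m + 1)] <- Conj(rot[2:(m + 1)])
  }
  if (n %% 2 == 0) rot[n / 2 + 1] <- sample(c(-1, 1), 1)
  sp <- mvfft(t(mat)) * rot
  t(Re(mvfft(sp, inverse = TRUE)) / n)
}

# internal: activation thresholds + masks + events for a pair of averages,
# using the ambient RNG stream (callers manage seeding)
fit_and_extract <- function(avg_list, set, bp_norm, times_ms,
                            act_alpha = 0.05, null_draws = 500,
                            min_run_ms = 50, match_window_ms = 200) {
  series <- lapply(avg_list, function(avg) {
    s <- fit_microstates(avg, set, times_ms = times_ms)
    avgc <- sweep(avg, 2, colMeans(avg))
    g <- gfp_columns(avgc)
    ok <- g > 0
    q <- rep(NA_real_, ncol(avgc))
    if (any(ok)) {
      draw <- bp_norm[sample.int(nrow(bp_norm), null_draws,
                                 replace = TRUE), , drop = FALSE]
      norm <- sweep(avgc[, ok, drop = FALSE], 2, g[ok], "/")
      r <- map_correlation(draw, t(norm))
      sc <- if (set$polarity_sensitive) pmax(r, 0) else abs(r)
      q[ok] <- apply(sc^2, 2, null_threshold, alpha = act_alpha)
    }
    active <- matrix(FALSE, nrow(s$c), ncol(s$c), dimnames = dimnames(s$c))
    for (mm in seq_len(nrow(s$c))) {
      raw <- !is.na(s$c[mm, ]) & !is.na(q) & s$c[mm, ] > q
      active[mm, ] <- run_length_filter(raw, times_ms, min_run_ms)$keep
    }
    s$active <- active
    s
  })
  md <- pooled_mean_durations(series)
  events <- lapply(series, extract_events, mean_durations = md)
  tfp <- vapply(seq_along(avg_list), function(i) {
    total_field_power(avg_list[[i]], times_ms = times_ms)
  }, 0)
  list(events = events, tfp = tfp, series = series)
}

# pair events of two groups: same template, occurrences matched greedily by
# onset proximity; kept when the intervals overlap or onsets are within
# match_window_ms
match_events <- function(ev_a, ev_b, match_window_ms = 200) {
  out <- list()
  for (id in intersect(ev_a$template_id, ev_b$template_id)) {
    a <- ev_a[ev_a$template_id == id, ]
    b <- ev_b[ev_b$template_id == id, ]
    used_b <- logical(nrow(b))
    for (i in seq_len(nrow(a))) {
      free <- which(!used_b)
      if (!length(free)) break
      j <- free[which.min(abs(b$onset_ms[free] - a$onset_ms[i]))]
      overlap <- a$onset_ms[i] < b$onset_ms[j] + b$duration_ms[j] &&
        b$onset_ms[j] < a$onset_ms[i] + a$duration_ms[i]
      if (overlap || abs(b$onset_ms[j] - a$onset_ms[i]) <= match_window_ms) {
        used_b[j] <- TRUE
        out[[length(out) + 1]] <- tibble::tibble(
          template_id = id,
          occurrence_a = a$occurrence[i], occurrence_b = b$occurrence[j],
          onset_a = a$onset_ms[i], onset_b = b$onset_ms[j],
          duration_a = a$duration_ms[i], duration_b = b$duration_ms[j],
          power_a = a$power_uvms[i], power_b = b$power_uvms[j]
        )
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(template_id = character(),
                          occurrence_a = integer(), occurrence_b = integer(),
                          onset_a = numeric(), onset_b = numeric(),
                          duration_a = numeric(), duration_b = numeric(),
                          power_a = numeric(), power_b = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Compare microstate parameters between groups against surrogate nulls
#'
#' Computes the observed between-group differences in microstate event
#' onset, duration and power (per matched event) and in total field power,
#' and tests each against a null built by generating two random groups of
#' the original sizes, refitting the microstates to the new averages, and
#' re-extracting the same parameters (null events anchored to the observed
#' events' latencies). Two schemes generate the random groups:
#'
#' * `"label_permutation"` (default): the original subjects are randomly
#'   reassigned between the groups. Under the null of identical group
#'   processes the subjects are exchangeable, so this yields an exactly
#'   calibrated difference null that preserves the common event structure.
#' * `"phase_surrogate"`: each subject is first replaced by the pooled
#'   (both-group) average plus a phase-randomized copy of that subject's
#'   residual around it (common random phases across channels, preserving
#'   the residual's spectra and instantaneous topographic structure while
#'   destroying any stimulus-locked, group-specific deviation), then
#'   regrouped. This destroys more structure and gives a wider,
#'   conservative null for latency parameters.
#'
#' Two-tailed p-values use the +1 permutation correction; the conventional
#' threshold is p < 0.05 two-tailed (0.025 per tail).
#'
#' @param group_a,group_b [epoch_set()]s fitted with the same template set.
#' @param set A `microstate_set`.
#' @param baseline_pool Baseline maps from [baseline_map_pool()] for the
#'   activation thresholds.
#' @param n_iter Number of surrogate iterations (default 5000).
#' @param seed Integer seed.
#' @param alpha_two_tailed Significance threshold on the two-tailed p
#'   (default 0.05, i.e. 0.025 per tail).
#' @param null_scheme How the random null groups are generated; see
#'   Details.
#' @param act_alpha,act_draws Activation-null level and draws per timepoint
#'   used when thresholding activations (defaults 0.05 and 500).
#' @param min_run_ms Minimum activation run (default 50 ms, 5% of a 1 s
#'   postlance period).
#' @param match_window_ms Events in the two groups are compared only at
#'   comparable latency: intervals must overlap or onsets fall within this
#'   window (default 200 ms).
#' @return Object of class `surrogate_comparison`: tibble `differences`
#'   with one row per (template, occurrence, parameter) plus
#'   `total_power`, columns `value_a`, `value_b`, `difference`, `p`,
#'   `n_null` (iterations in which the event re-occurred and matched), and
#'   `significant`. Events present in only one group are reported in
#'   `unmatched` as incomparable.
#' @export
surrogate_compare <- function(group_a, group_b, set, baseline_pool,
                              n_iter = 5000, seed = 1L,
                              alpha_two_tailed = 0.05,
                              null_scheme = c("label_permutation",
                                              "phase_surrogate"),
                              act_alpha = 0.05, act_draws = 500,
                              min_run_ms = 50, match_window_ms = 200) {
  null_scheme <- match.arg(null_scheme)
  check_same_grid(group_a, group_b)
  na <- dim(group_a$data)[1]
  nb <- dim(group_b$data)[1]
  times <- group_a$times_ms
  bp <- baseline_pool - rowMeans(baseline_pool)
  bg <- apply(bp, 1, gfp)
  bp_norm <- bp[bg > 0, , drop = FALSE] / bg[bg > 0]
  with_seed(seed, {
    obs <- fit_and_extract(list(grand_average(group_a),
                                grand_average(group_b)),
                           set, bp_norm, times, act_alpha, act_draws,
                           min_run_ms, match_window_ms)
    matched <- match_events(obs$events[[1]], obs$events[[2]],
                            match_window_ms)
    keys <- if (nrow(matched)) {
      tibble::tibble(template_id = matched$template_id,
                     occurrence = matched$occurrence_a)
    } else {
      tibble::tibble(template_id = character(), occurrence = integer())
    }
    obs_diff <- observed_differences(matched, obs$tfp)
    # null accumulation: one column per observed difference row; null
    # events are anchored to the observed events' latencies so spurious
    # distant runs cannot stand in for them
    nulls <- matrix(NA_real_, n_iter, nrow(obs_diff))
    X <- rbind(flatten_epochs(group_a), flatten_epochs(group_b))
    nch <- length(group_a$montage)
    pooled_mean <- colMeans(X)
    for (it in seq_len(n_iter)) {
      surr <- if (null_scheme == "label_permutation") {
        X
      } else {
        s2 <- matrix(NA_real_, na + nb, ncol(X))
        for (s in seq_len(na + nb)) {
          resid <- matrix(X[s, ] - pooled_mean, nch)
          s2[s, ] <- pooled_mean + as.vector(phase_randomize(resid))
        }
        s2
      }
      ia <- sample.int(na + nb, na)
      avg_a <- matrix(colMeans(surr[ia, , drop = FALSE]), nch)
      avg_b <- matrix(colMeans(surr[-ia, , drop = FALSE]), nch)
      ft <- fit_and_extract(list(avg_a, avg_b), set, bp_norm, times,
                            act_alpha, act_draws, min_run_ms,
                            match_window_ms)
      nulls[it, ] <- null_differences(obs_diff, matched, ft,
                                      match_window_ms)
    }
    p <- vapply(seq_len(nrow(obs_diff)), function(j) {
      nv <- nulls[, j]
      nv <- nv[!is.na(nv)]
      if (!length(nv)) return(NA_real_)
      pr <- (1 + sum(nv >= obs_diff$difference[j])) / (1 + length(nv))
      pl <- (1 + sum(nv <= obs_diff$difference[j])) / (1 + length(nv))
      min(1, 2 * min(pr, pl))
    }, 0)
    n_null <- colSums(!is.na(nulls))
    differences <- dplyr::mutate(
      obs_diff, p = p, n_null = n_null,
      significant = !is.na(p) & p < alpha_two_tailed)
    keys_b <- if (nrow(matched)) {
      tibble::tibble(template_id = matched$template_id,
                     occurrence = matched$occurrence_b)
    } else {
      tibble::tibble(template_id = character(), occurrence = integer())
    }
    unmatched <- dplyr::bind_rows(
      dplyr::anti_join(dplyr::mutate(obs$events[[1]], group = "group_a"),
                       keys, by = c("template_id", "occurrence")),
      dplyr::anti_join(dplyr::mutate(obs$events[[2]], group = "group_b"),
                       keys_b, by = c("template_id", "occurrence"))
    )
    structure(list(differences = differences, unmatched = unmatched,
                   events_a = obs$events[[1]], events_b = obs$events[[2]],
                   n_iter = n_iter, seed = seed,
                   null_scheme = null_scheme,
                   alpha_two_tailed = alpha_two_tailed),
              class = "surrogate_comparison")
  })
}

# nearest same-template event to an anchor onset, or NULL when none falls
# within the comparable-latency window
nearest_event <- function(events, id, anchor_onset, match_window_ms) {
  e <- events[events$template_id == id, ]
  if (!nrow(e)) return(NULL)
  j <- which.min(abs(e$onset_ms - anchor_onset))
  overlap <- e$onset_ms[j] < anchor_onset + match_window_ms &&
    anchor_onset < e$onset_ms[j] + e$duration_ms[j]
  if (!overlap && abs(e$onset_ms[j] - anchor_onset) > match_window_ms) {
    return(NULL)
  }
  e[j, ]
}

# one null iteration's differences, aligned to the observed difference rows
null_differences <- function(obs_diff, matched, ft, match_window_ms) {
  out <- rep(NA_real_, nrow(obs_diff))
  if (nrow(matched)) {
    for (i in seq_len(nrow(matched))) {
      ea <- nearest_event(ft$events[[1]], matched$template_id[i],
                          matched$onset_a[i], match_window_ms)
      eb <- nearest_event(ft$events[[2]], matched$template_id[i],
                          matched$onset_b[i], match_window_ms)
      if (is.null(ea) || is.null(eb)) next
      for (par in c("onset", "duration", "power")) {
        j <- which(obs_diff$template_id == matched$template_id[i] &
                     obs_diff$occurrence == matched$occurrence_a[i] &
                     obs_diff$parameter == par)
        col <- switch(par, onset = "onset_ms", duration = "duration_ms",
                      power = "power_uvms")
        out[j] <- eb[[col]] - ea[[col]]
      }
    }
  }
  out[obs_diff$parameter == "total_power"] <- ft$tfp[2] - ft$tfp[1]
  out
}

observed_differences <- function(matched, tfp) {
  rows <- list()
  if (nrow(matched)) {
    for (i in seq_len(nrow(matched))) {
      for (par in c("onset", "duration", "power")) {
        va <- matched[[paste0(par, "_a")]][i]
        vb <- matched[[paste0(par, "_b")]][i]
        rows[[length(rows) + 1]] <- tibble::tibble(
          template_id = matched$template_id[i],
          occurrence = matched$occurrence_a[i],
          parameter = par, value_a = va, value_b = vb,
          difference = vb - va)
      }
    }
  }
  rows[[length(rows) + 1]] <- tibble::tibble(
    template_id = "(all)", occurrence = 0L, parameter = "total_power",
    value_a = tfp[1], value_b = tfp[2], difference = tfp[2] - tfp[1])
  dplyr::bind_rows(rows)
}

#' @export
print.surrogate_comparison <- function(x, ...) {
  cat(sprintf("<surrogate_comparison> %d parameter difference(s), %d iterations\n",
              nrow(x$differences), x$n_iter))
  sig <- x$differences[x$differences$significant, ]
  cat(sprintf("  %d significant at two-tailed p < %.3g\n", nrow(sig),
              x$alpha_two_tailed))
  invisible(x)
}

#' @export
tidy.surrogate_comparison <- function(x, ...) x$differences

#' @export
glance.surrogate_comparison <- function(x, ...) {
  tibble::tibble(n_iter = x$n_iter, alpha_two_tailed = x$alpha_two_tailed,
                 n_parameters = nrow(x$differences),
                 n_significant = sum(x$differences$significant),
                 n_unmatched_events = nrow(x$unmatched))
}
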