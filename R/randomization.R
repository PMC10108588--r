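new_randomization_result <- function(method, times_ms, statistic, p,
                                     alpha, min_run_ms, n_iter, seed,
                                     null_q = NULL, extra = list()) {
  filt <- run_length_filter(p < alpha, times_ms, min_run_ms)
  structure(
    c(list(method = method, times_ms = times_ms, statistic = statistic,
           p = p, alpha = alpha, min_run_ms = min_run_ms,
           n_iter = n_iter, seed = seed, null_q95 = null_q,
           significant_raw = p < alpha, significant = filt$keep,
           segments = filt$segments),
      extra),
    class = "randomization_result"
  )
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf("<randomization_result: %s> %d timepoints, %d iterations\n",
              x$method, length(x$times_ms), x$n_iter))
  cat(sprintf("  alpha %.3g, minimum run %g ms; %d significant segment(s)\n",
              x$alpha, x$min_run_ms, nrow(x$segments)))
  if (nrow(x$segments)) {
    for (i in seq_len(nrow(x$segments))) {
      cat(sprintf("    [%g, %g) ms\n", x$segments$start_ms[i],
                  x$segments$end_ms[i]))
    }
  }
  invisible(x)
}

#' Tidy a randomization test result
#'
#' @param x A `randomization_result` from [tanova()], [tct()] or
#'   [activation_significance()].
#' @param ... Unused.
#' @return Tibble with one row per timepoint: `time_ms`, `statistic`, `p`,
#'   `significant_raw` (before run-length control) and `significant`.
#' @export
tidy.randomization_result <- function(x, ...) {
  tibble::tibble(time_ms = x$times_ms, statistic = x$statistic, p = x$p,
                 significant_raw = x$significant_raw,
                 significant = x$significant)
}

#' @export
glance.randomization_result <- function(x, ...) {
  tibble::tibble(method = x$method, n_iter = x$n_iter, alpha = x$alpha,
                 min_run_ms = x$min_run_ms,
                 n_segments = nrow(x$segments),
                 frac_significant = mean(x$significant),
                 frac_significant_raw = mean(x$significant_raw))
}

#' Topographic ANOVA: randomization test of map differences between groups
#'
#' At every timepoint the dissimilarity index (DISS) between the two group
#' average maps measures how different the scalp field configurations are.
#' Its null distribution is built by shuffling subjects across the two
#' groups (preserving group sizes) and recomputing the DISS; the p-value is
#' the right-tailed exceedance fraction with the +1 correction, so the
#' identity permutation is part of the null set and p-values are valid.
#' Multiple comparisons over time are controlled by keeping only runs of
#' significant timepoints covering at least `min_run_frac` (default 5%) of
#' the tested window.
#'
#' @param group_a,group_b [epoch_set()]s over the same montage, sampling
#'   rate and time axis.
#' @param window_ms Tested window `(start, end)` in ms; default the full
#'   epoch.
#' @param n_iter Number of label permutations (default 5000).
#' @param alpha Per-timepoint significance level (default 0.05,
#'   right-tailed).
#' @param seed Integer seed for the permutations.
#' @param min_run_frac Minimum continuous run as a fraction of the window
#'   duration (default 0.05, e.g. 75 ms for a 1500 ms window).
#' @param normalize Compute the DISS on GFP-normalized maps (default TRUE,
#'   the standard definition); `FALSE` uses the unnormalized RMS map
#'   difference.
#' @return A `randomization_result`; timepoints where either average has
#'   zero GFP get p = 1 (the DISS is undefined there).
#' @export
tanova <- function(group_a, group_b, window_ms = NULL, n_iter = 5000,
                   alpha = 0.05, seed = 1L, min_run_frac = 0.05,
                   normalize = TRUE) {
  check_same_grid(group_a, group_b)
  na <- dim(group_a$data)[1]
  nb <- dim(group_b$data)[1]
  if (na < 2 || nb < 2) abort("each group needs at least 2 subjects")
  if (is.null(window_ms)) {
    window_ms <- c(group_a$times_ms[1],
                   group_a$times_ms[length(group_a$times_ms)] +
                     1000 / group_a$fs_hz)
  }
  ga <- window_epochs(group_a, window_ms)
  gb <- window_epochs(group_b, window_ms)
  nch <- length(ga$montage)
  nt <- length(ga$times_ms)
  X <- rbind(flatten_epochs(ga), flatten_epochs(gb))
  stat_fun <- function(ia) {
    a <- matrix(colMeans(X[ia, , drop = FALSE]), nch)
    b <- matrix(colMeans(X[-ia, , drop = FALSE]), nch)
    if (normalize) diss_columns(a, b) else sqrt(colMeans((a - b)^2))
  }
  obs <- stat_fun(seq_len(na))
  if (all(is.na(obs))) abort("degenerate all-zero group averages")
  with_seed(seed, {
    exceed <- integer(nt)
    valid <- !is.na(obs)
    for (i in seq_len(n_iter)) {
      perm <- sample.int(na + nb, na)
      nullstat <- stat_fun(perm)
      exceed <- exceed + (!is.na(nullstat) & valid & nullstat >= obs)
    }
    p <- (1 + exceed) / (1 + n_iter)
    p[!valid] <- 1
    new_randomization_result(
      "tanova", ga$times_ms, obs, p, alpha,
      min_run_frac * (window_ms[2] - window_ms[1]), n_iter, seed)
  })
}

#' Topographic consistency test within a group
#'
#' Asks, at every timepoint, whether subjects share a common scalp
#' topography: the observed statistic is the GFP of the grand-average map,
#' which is large only when individual maps align. The null shuffles each
#' subject's data across electrodes independently (destroying cross-subject
#' channel consistency while keeping each subject's value distribution) and
#' recomputes the grand-average GFP. Timepoints exceeding the 95th
#' percentile of the null (right-tailed, with the +1 correction) in runs of
#' at least `min_run_frac` of the window are consistent. The tested window
#' starts by default 200 ms before the stimulus trigger to absorb the
#' uncertainty in the exact release of the lance.
#'
#' @param group An [epoch_set()] with at least 3 subjects.
#' @param window_ms Tested window; default `c(-200, 1000)` ms.
#' @inheritParams tanova
#' @return A `randomization_result` whose `significant` mask marks the
#'   topographically consistent timepoints.
#' @export
tct <- function(group, window_ms = c(-200, 1000), n_iter = 5000,
                alpha = 0.05, seed = 1L, min_run_frac = 0.05) {
  stopifnot(inherits(group, "epoch_set"))
  ns <- dim(group$data)[1]
  nch <- dim(group$data)[2]
  if (ns < 3) abort("TCT needs at least 3 subjects")
  if (nch < 2) abort("TCT needs at least 2 channels")
  g <- window_epochs(group, window_ms)
  nt <- length(g$times_ms)
  obs <- gfp_columns(grand_average(g))
  with_seed(seed, {
    exceed <- integer(nt)
    for (i in seq_len(n_iter)) {
      acc <- matrix(0, nch, nt)
      for (s in seq_len(ns)) {
        acc <- acc + g$data[s, sample.int(nch), ]
      }
      exceed <- exceed + (gfp_columns(acc / ns) >= obs)
    }
    p <- (1 + exceed) / (1 + n_iter)
    new_randomization_result(
      "tct", g$times_ms, obs, p, alpha,
      min_run_frac * (window_ms[2] - window_ms[1]), n_iter, seed)
  })
}

check_same_grid <- function(a, b) {
  stopifnot(inherits(a, "epoch_set"), inherits(b, "epoch_set"))
  if (!identical(a$montage, b$montage)) abort("groups must share a montage")
  if (a$fs_hz != b$fs_hz) abort("groups must share a sampling rate")
  if (length(a$times_ms) != length(b$times_ms) ||
      max(abs(a$times_ms - b$times_ms)) > 1e-9) {
    abort("groups must share a time axis")
  }
  invisible(TRUE)
}
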