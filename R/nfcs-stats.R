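#' Compare NFCS constellations within and between cohorts
#'
#' Facial-action totals are bounded counts and typically far from normal,
#' so the constellation comparison is fully nonparametric: a Friedman
#' analysis of variance across the paired constellations, post hoc pairwise
#' Wilcoxon signed-rank tests (Z from the tie-corrected normal
#' approximation with continuity correction; exact p below `exact_below`
#' untied pairs), and, when a grouping column is supplied, Mann-Whitney U
#' tests comparing each constellation between the two cohorts.
#'
#' @param scores Tibble with columns `subject_id`, `constellation`, `total`
#'   (one epoch's totals), and optionally `group` (exactly 2 levels) for the
#'   between-cohort tests.
#' @param exact_below Use exact signed-rank/rank-sum p-values when the
#'   effective sample size is below this (and there are no ties);
#'   default 10.
#' @return List of tibbles: `friedman` (`chisq`, `df`, `p`), `pairwise`
#'   (Wilcoxon `Z`, `p` per constellation pair) and `between_groups`
#'   (Mann-Whitney `U`, `Z`, `p` per constellation; `NULL` without groups).
#' @export
compare_constellations <- function(scores, exact_below = 10) {
  cons <- unique(scores$constellation)
  if (length(cons) < 2) abort("need at least 2 constellations")
  wide <- scores |>
    dplyr::select("subject_id", "constellation", "total") |>
    tidyr::pivot_wider(names_from = "constellation", values_from = "total") |>
    tidyr::drop_na()
  if (nrow(wide) < 3) abort("Friedman test needs at least 3 complete subjects")
  m <- as.matrix(wide[, cons])
  fr <- stats::friedman.test(m)
  chisq <- unname(fr$statistic)
  p <- fr$p.value
  if (!is.finite(chisq)) {      # complete ties: no evidence of a difference
    chisq <- 0
    p <- 1
  }
  friedman <- tibble::tibble(chisq = chisq, df = unname(fr$parameter),
                             p = p)
  pairs <- utils::combn(cons, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    w <- wilcoxon_signed_rank(m[, pr[1]], m[, pr[2]], exact_below)
    tibble::tibble(a = pr[1], b = pr[2], Z = w$Z, p = w$p)
  })
  between <- NULL
  if ("group" %in% names(scores) &&
      length(unique(scores$group)) == 2) {
    gl <- sort(unique(scores$group))
    between <- purrr::map_dfr(cons, function(cc) {
      x <- scores$total[scores$constellation == cc & scores$group == gl[1]]
      y <- scores$total[scores$constellation == cc & scores$group == gl[2]]
      mw <- mann_whitney(x, y, exact_below)
      tibble::tibble(constellation = cc, U = mw$U, Z = mw$Z, p = mw$p)
    })
  }
  list(friedman = friedman, pairwise = pairwise, between_groups = between)
}

# Wilcoxon signed-rank: Z from tie-corrected normal approximation with
# continuity correction; exact p by full sign-flip enumeration (with the
# observed, possibly tied, average ranks) for small samples
wilcoxon_signed_rank <- function(a, b, exact_below = 10) {
  d <- b - a
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(Z = 0, p = 1))
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  cc <- if (w_pos != mu) 0.5 * sign(w_pos - mu) else 0
  Z <- if (sig2 > 0) (w_pos - mu - cc) / sqrt(sig2) else 0
  p <- if (n < exact_below) {
    # null: each |d| rank signed + with probability 1/2
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_null <- as.vector(signs %*% r)
    lo <- mean(w_null <= w_pos)
    hi <- mean(w_null >= w_pos)
    2 * min(lo, hi)
  } else {
    2 * stats::pnorm(-abs(Z))
  }
  list(Z = Z, p = min(p, 1))
}

# Mann-Whitney U with tie-corrected normal approximation
mann_whitney <- function(x, y, exact_below = 10) {
  nx <- length(x)
  ny <- length(y)
  if (nx < 1 || ny < 1) abort("both groups must be nonempty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  nt <- nx + ny
  ties <- table(r)
  sig2 <- nx * ny / 12 *
    ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
  cc <- if (U != mu) 0.5 * sign(U - mu) else 0
  Z <- if (sig2 > 0) (U - mu - cc) / sqrt(sig2) else 0
  has_ties <- any(duplicated(c(x, y)))
  p <- if (min(nx, ny) < exact_below && !has_ties) {
    suppressWarnings(stats::wilcox.test(x, y, exact = TRUE)$p.value)
  } else {
    2 * stats::pnorm(-abs(Z))
  }
  list(U = U, Z = Z, p = min(p, 1))
}

#' Two-way random-effects intraclass correlation, ICC(2,1)
#'
#' Single-rater, absolute-agreement intraclass correlation under the
#' two-way random-effects model, the usual index of interrater reliability
#' for facial-action coding:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' with subjects' mean square MSR, raters' mean square MSC and residual
#' MSE from the two-way ANOVA decomposition.
#'
#' @param ratings Numeric matrix, subjects x raters, complete.
#' @return Scalar ICC in `[-1, 1]`. With no between-subject variance the
#'   coefficient is undefined; 0 is returned with a warning.
#' @export
icc_two_way <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2 || k < 2) abort("need at least 2 subjects and 2 raters")
  if (anyNA(ratings)) abort("ratings must be complete")
  grand <- mean(ratings)
  rowm <- rowMeans(ratings)
  colm <- colMeans(ratings)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  sse <- sum((ratings - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (max(abs(rowm - grand)) < .Machine$double.eps^0.5 || denom <= 0) {
    warn("no between-subject variance: ICC undefined, returning 0")
    return(0)
  }
  (msr - mse) / denom
}
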