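#' Pooled-variance two-sample t statistic from summary data
#'
#' Computes the classic equal-variance two-sample t statistic from group
#' means, standard deviations and sizes, as used for demographic
#' comparisons reported as mean (SD) per group:
#' `t = (mean_a - mean_b) / (s_p * sqrt(1/n_a + 1/n_b))` with
#' `s_p^2 = ((n_a-1) sd_a^2 + (n_b-1) sd_b^2) / (n_a + n_b - 2)`.
#' A Welch (unequal-variance) version is available via `welch = TRUE`.
#'
#' @param mean_a,sd_a,n_a Summary statistics of group A (`n_a >= 2`).
#' @param mean_b,sd_b,n_b Summary statistics of group B (`n_b >= 2`).
#' @param welch Use the Welch statistic and Satterthwaite df instead of
#'   pooling (default FALSE).
#' @return Tibble with `t`, `df`, `p` (two-sided). Zero pooled variance
#'   gives t = 0 for equal means and signed infinity (with a warning)
#'   otherwise.
#' @export
#' @examples
#' pooled_t(35.24, 1.03, 41, 38.91, 1.18, 37) # t = -14.66
pooled_t <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b, welch = FALSE) {
  if (n_a < 2 || n_b < 2) abort("both groups need n >= 2")
  if (sd_a < 0 || sd_b < 0) abort("standard deviations must be non-negative")
  d <- mean_a - mean_b
  if (welch) {
    va <- sd_a^2 / n_a
    vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  } else {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2) * sqrt(1 / n_a + 1 / n_b)
    df <- n_a + n_b - 2
  }
  if (se == 0) {
    if (d == 0) {
      t <- 0
    } else {
      warn("zero variance with unequal means: t is infinite")
      t <- sign(d) * Inf
    }
  } else {
    t <- d / se
  }
  tibble::tibble(t = t, df = df,
                 p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square statistic for a 2x2 table
#'
#' Uncorrected (no continuity correction) Pearson chi-square for a 2x2
#' contingency table with cells `a, b` (row 1) and `c, d` (row 2):
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`. Used for sex-ratio
#' comparisons between cohorts.
#'
#' @param a,b,c,d Non-negative integer counts; all margins must be
#'   positive.
#' @return Tibble with `chisq`, `df` (= 1) and `p`.
#' @export
#' @examples
#' chi_square_2x2(24, 17, 12, 25) # 5.33
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  if (any(c(a + b, c + d, a + c, b + d) == 0)) {
    abort("all table margins must be positive")
  }
  n <- a + b + c + d
  chisq <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  tibble::tibble(chisq = chisq, df = 1,
                 p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

#' Demographic comparison table from per-variable summaries
#'
#' Reproduces the standard participant-demographics table: pooled t tests
#' for continuous variables supplied as mean (SD) n per group, and
#' uncorrected chi-square tests for 2x2 count variables.
#'
#' @param continuous Tibble with columns `variable`, `mean_a`, `sd_a`,
#'   `n_a`, `mean_b`, `sd_b`, `n_b`; may be NULL.
#' @param counts Tibble with columns `variable`, `a`, `b`, `c`, `d`
#'   (2x2 cells per variable); may be NULL.
#' @return Tibble: `variable`, `statistic` (`"t"` or `"chisq"`), `value`,
#'   `df`, `p`.
#' @export
demographic_table <- function(continuous = NULL, counts = NULL) {
  out <- list()
  if (!is.null(continuous)) {
    out$t <- purrr::pmap_dfr(continuous, function(variable, mean_a, sd_a,
                                                  n_a, mean_b, sd_b, n_b,
                                                  ...) {
      r <- pooled_t(mean_a, sd_a, n_a, mean_b, sd_b, n_b)
      tibble::tibble(variable = variable, statistic = "t", value = r$t,
                     df = r$df, p = r$p)
    })
  }
  if (!is.null(counts)) {
    out$chisq <- purrr::pmap_dfr(counts, function(variable, a, b, c, d,
                                                  ...) {
      r <- chi_square_2x2(a, b, c, d)
      tibble::tibble(variable = variable, statistic = "chisq",
                     value = r$chisq, df = r$df, p = r$p)
    })
  }
  dplyr::bind_rows(out)
}
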