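make_scores <- function(m, cons = colnames(m)) {
  tibble::tibble(
    subject_id = rep(sprintf("S%02d", seq_len(nrow(m))), times = ncol(m)),
    constellation = rep(cons, each = nrow(m)),
    total = as.vector(m)
  )
}

test_that("identical paired columns give a null Friedman test", {
  m <- cbind(a = c(3, 7, 5, 9, 2), b = c(3, 7, 5, 9, 2),
             c = c(3, 7, 5, 9, 2))
  r <- compare_constellations(make_scores(m))
  expect_equal(r$friedman$chisq, 0)
  expect_equal(r$friedman$p, 1)
  expect_equal(r$friedman$df, 2)
})

test_that("a constant within-pair shift yields the maximal Wilcoxon Z", {
  n <- 12
  set.seed(51)
  a <- rnorm(n)
  m <- cbind(a = a, b = a + 1)
  r <- compare_constellations(make_scores(m))
  # all differences positive and equal: W+ at its maximum n(n+1)/2, with
  # every |d| tied (one tie group of size n in the variance correction)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - (n^3 - n) / 48
  z_max <- (n * (n + 1) / 4 - 0.5) / sqrt(sig2)
  expect_equal(abs(r$pairwise$Z), z_max, tolerance = 1e-12)
  # and the exact enumeration agrees at small n
  n2 <- 6
  m2 <- cbind(a = rnorm(n2), b = 0)
  m2[, "b"] <- m2[, "a"] + 1
  r2 <- compare_constellations(make_scores(m2))
  expect_equal(r2$pairwise$p, 2 / 2^n2, tolerance = 1e-12)  # 2 * P(all +)
})

test_that("Mann-Whitney holds its nominal type-I error rate", {
  set.seed(52)
  rej <- 0
  nsim <- 1000
  for (i in seq_len(nsim)) {
    x <- rnorm(15)
    y <- rnorm(15)
    if (painstates:::mann_whitney(x, y)$p < 0.05) rej <- rej + 1
  }
  se <- sqrt(0.05 * 0.95 / nsim)
  expect_lt(abs(rej / nsim - 0.05), 3 * se + 1e-9)
})

test_that("rank statistics agree with the reference implementations", {
  set.seed(53)
  for (i in 1:50) {
    x <- rnorm(14)
    y <- rnorm(17)
    mw <- painstates:::mann_whitney(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_equal(mw$U, unname(ref$statistic))
    expect_equal(2 * pnorm(-abs(mw$Z)), ref$p.value, tolerance = 1e-10)
    z <- x + rnorm(14)
    w <- painstates:::wilcoxon_signed_rank(x, z)
    refw <- suppressWarnings(stats::wilcox.test(z, x, paired = TRUE,
                                                exact = FALSE,
                                                correct = TRUE))
    expect_equal(2 * pnorm(-abs(w$Z)), refw$p.value, tolerance = 1e-10)
  }
})

test_that("the two-way random-effects ICC behaves across agreement regimes", {
  # identical rater columns with between-subject variance
  subj <- c(1, 5, 9, 13, 2, 8)
  expect_equal(icc_two_way(cbind(subj, subj, subj)), 1)
  # independent raters: near zero at large n
  set.seed(54)
  a <- rnorm(400)
  expect_lt(abs(icc_two_way(cbind(a, sample(a)))), 0.15)
  # hand-computed mean squares on a small matrix
  m <- matrix(c(9, 2, 5, 8,
                6, 1, 3, 2,
                8, 4, 6, 8,
                7, 1, 2, 6,
                10, 5, 6, 9,
                6, 2, 4, 7), ncol = 4, byrow = TRUE)
  n <- nrow(m); k <- ncol(m)
  g <- mean(m)
  msr <- k * sum((rowMeans(m) - g)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - g)^2) / (k - 1)
  mse <- (sum((m - g)^2) - (n - 1) * msr / k * k - (k - 1) * msc / n * n) /
    ((n - 1) * (k - 1))
  byhand <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(icc_two_way(m), byhand, tolerance = 1e-12)
  # zero between-subject variance: defined limit 0 with a warning
  expect_warning(z <- icc_two_way(rbind(c(1, 2), c(1, 2), c(1, 2))),
                 "undefined")
  expect_equal(z, 0)
  expect_error(icc_two_way(matrix(1:2, 2, 1)), "2 subjects and 2 raters")
})

test_that("between-group Mann-Whitney comparisons run per constellation", {
  set.seed(55)
  sc <- tibble::tibble(
    subject_id = rep(sprintf("S%02d", 1:20), times = 2),
    group = rep(rep(c("g1", "g2"), each = 10), times = 2),
    constellation = rep(c("nfcs_p3", "nfcs7"), each = 20),
    total = c(rnorm(10, 20), rnorm(10, 5), rnorm(10, 40), rnorm(10, 12))
  )
  r <- compare_constellations(sc)
  expect_equal(nrow(r$between_groups), 2)
  expect_true(all(r$between_groups$p < 0.01))
})
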