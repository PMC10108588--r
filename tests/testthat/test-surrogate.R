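test_that("phase randomization preserves spectra and channel covariance", {
  set.seed(91)
  for (n in c(128, 129)) {                    # even and odd lengths
    x <- matrix(rnorm(6 * n), 6)
    y <- painstates:::with_seed(92, phase_randomize(x))
    # per-channel amplitude spectra identical
    for (ch in 1:6) {
      expect_equal(Mod(fft(y[ch, ])), Mod(fft(x[ch, ])), tolerance = 1e-6)
    }
    # common rotation preserves cross-spectra, hence the time-averaged
    # channel covariance
    expect_equal(tcrossprod(y), tcrossprod(x), tolerance = 1e-6)
    # but the time courses themselves are scrambled
    expect_gt(max(abs(y - x)), 0.1)
  }
})

test_that("comparing a group with itself yields zero differences and null p", {
  tm <- fixed_templates(2)
  coh <- small_cohort(n = 8, snr = 10, fs = 125, seed = 93)
  es <- coh$epochs$group1
  tmn <- tm
  colnames(tmn) <- default_montage()
  set <- cluster_microstates(tmn, 2)
  bp <- baseline_map_pool(es, c(-500, 0))
  cmp <- surrogate_compare(es, es, set, bp, n_iter = 60, seed = 94,
                           act_draws = 200)
  expect_true(all(cmp$differences$difference == 0))
  expect_true(all(cmp$differences$p[!is.na(cmp$differences$p)] > 0.5))
  expect_false(any(cmp$differences$significant, na.rm = TRUE))
})

test_that("a planted onset shift is detected with the right sign", {
  tm <- fixed_templates(2)
  sc_a <- small_script(tm, snr = 10, jitter_sd_ms = 5)
  sc_b <- small_script(tm, snr = 10, jitter_sd_ms = 5,
                       onsets = c(100, 560))   # second state 60 ms later
  coh <- generate_erp_cohort(cohort_spec(20, list(sc_a, sc_b), fs_hz = 125,
                                         seed = 95))
  tmn <- tm
  colnames(tmn) <- default_montage()
  set <- cluster_microstates(tmn, 2)
  bp <- baseline_map_pool(coh$epochs, c(-500, 0))
  cmp <- surrogate_compare(coh$epochs$group1, coh$epochs$group2, set, bp,
                           n_iter = 300, seed = 96, act_draws = 200)
  ord <- apply(abs(painstates:::map_correlation(set$templates, tm)), 2,
               which.max)
  shifted <- cmp$differences[
    cmp$differences$template_id == paste0("MS", ord[2]) &
      cmp$differences$parameter == "onset", ]
  expect_equal(nrow(shifted), 1)
  expect_gt(shifted$difference, 30)            # sign-correct, ~+60 ms
  expect_lt(shifted$p, 0.05)
  expect_true(shifted$significant)
})

test_that("unmatched events are reported as incomparable, not differenced", {
  tm <- fixed_templates(3)
  sc_a <- small_script(tm[1:2, ], snr = 10, jitter_sd_ms = 0)
  # group B engages a third state A never visits
  sc_b <- microstate_script(
    tibble::tibble(template_id = c("M1", "M2", "M3"),
                   onset_ms = c(100, 500, 800),
                   duration_ms = c(200, 200, 150),
                   amplitude_uv = 4),
    tm, jitter_sd_ms = 0, snr = 10)
  coh <- generate_erp_cohort(cohort_spec(10, list(sc_a, sc_b), fs_hz = 125,
                                         seed = 97))
  tmn <- tm
  colnames(tmn) <- default_montage()
  set <- cluster_microstates(tmn, 3)
  bp <- baseline_map_pool(coh$epochs, c(-500, 0))
  cmp <- surrogate_compare(coh$epochs$group1, coh$epochs$group2, set, bp,
                           n_iter = 30, seed = 98, act_draws = 200)
  ord <- apply(abs(painstates:::map_correlation(set$templates, tm)), 2,
               which.max)
  third <- paste0("MS", ord[3])
  expect_false(third %in% cmp$differences$template_id)
  expect_true(third %in% cmp$unmatched$template_id)
})
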