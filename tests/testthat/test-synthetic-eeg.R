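test_that("noise-free cohorts render the scripted topography exactly", {
  tm <- fixed_templates(1)
  sc <- small_script(tm, snr = Inf, jitter_sd_ms = 0,
                     onsets = 100, durations = 200)
  coh <- generate_erp_cohort(cohort_spec(3, list(sc, sc), fs_hz = 250,
                                         seed = 5))
  avg <- painstates:::grand_average(coh$epochs$group1)
  i200 <- which.min(abs(coh$epochs$group1$times_ms - 200))
  expect_equal(abs(cor(avg[, i200], tm[1, ])), 1, tolerance = 1e-9)
})

test_that("zero-amplitude scripts leave pure seeded noise", {
  tm1 <- fixed_templates(1, seed = 1)
  tm2 <- fixed_templates(1, seed = 2)
  mk <- function(tm) {
    sc <- microstate_script(
      tibble::tibble(template_id = rownames(tm), onset_ms = 100,
                     duration_ms = 200, amplitude_uv = 0),
      tm, jitter_sd_ms = 0, snr = 5)
    generate_erp_cohort(cohort_spec(3, list(sc, sc), fs_hz = 250, seed = 9))
  }
  a <- mk(tm1)
  b <- mk(tm2)
  # with no signal, templates are irrelevant: noise-only output, same seed
  expect_identical(a$epochs$group1$data, b$epochs$group1$data)
  expect_gt(mean(painstates:::gfp_columns(
    painstates:::grand_average(a$epochs$group1))), 0)
})

test_that("winner-take-all assignment at interval midpoints recovers the script", {
  tm <- fixed_templates(2)
  coh <- small_cohort(n = 20, snr = 10, seed = 31)
  es <- coh$epochs$group1
  mids <- c(200, 600)                    # midpoints of [100,300) and [500,700)
  hits <- 0
  for (s in seq_len(20)) {
    for (j in 1:2) {
      i <- which.min(abs(es$times_ms - mids[j]))
      r <- abs(c(cor(es$data[s, , i], tm[1, ]), cor(es$data[s, , i], tm[2, ])))
      hits <- hits + (which.max(r) == j)
    }
  }
  expect_gte(hits / 40, 0.95)
})

test_that("generation is seed-deterministic and average-referenced", {
  a <- small_cohort(n = 3, seed = 77)
  b <- small_cohort(n = 3, seed = 77)
  expect_identical(a$epochs$group1$data, b$epochs$group1$data)
  expect_identical(a$ground_truth, b$ground_truth)
  mu <- apply(a$epochs$group2$data, c(1, 3), mean)
  expect_lt(max(abs(mu)), 1e-9)
})

test_that("realized SNR matches the requested SNR", {
  tm <- fixed_templates(2)
  sc <- small_script(tm, snr = 4, jitter_sd_ms = 5)
  spec <- cohort_spec(20, list(sc, sc), fs_hz = 250, seed = 13)
  coh <- generate_erp_cohort(spec)
  es <- coh$epochs$group1
  times <- es$times_ms
  ratios <- vapply(seq_len(20), function(s) {
    gt <- coh$ground_truth[coh$ground_truth$subject_id ==
                             es$subject_ids[s], ]
    sig <- matrix(0, 18, length(times))
    for (i in seq_len(nrow(gt))) {
      env <- painstates:::event_envelope(times, gt$onset_ms[i],
                                         gt$duration_ms[i], sc$ramp_ms)
      sig <- sig + gt$amplitude_uv[i] * tm[gt$template_id[i], ] %o% env
    }
    noise <- es$data[s, , ] - rereference_common_average(sig)
    mean(sig^2) / mean(noise^2)
  }, 0)
  expect_true(all(abs(ratios - 4) / 4 < 0.1))
})

test_that("scripted events outside the epoch are rejected", {
  tm <- fixed_templates(1)
  sc <- small_script(tm, onsets = 950, durations = 200)
  expect_error(cohort_spec(3, list(sc, sc), seed = 1), "outside the epoch")
  sc2 <- small_script(tm, onsets = -600, durations = 50)
  expect_error(cohort_spec(3, list(sc2, sc2), seed = 1), "outside the epoch")
})

test_that("script validation enforces template normalization and ordering", {
  tm <- fixed_templates(2)
  expect_error(small_script(tm * 2), "unit GFP")
  expect_error(small_script(tm + 1), "average-referenced")
  sc <- small_script(tm, onsets = c(500, 100))
  expect_equal(sc$entries$onset_ms, c(100, 500))   # sorted on construction
  bad <- tibble::tibble(template_id = "M1", onset_ms = 0,
                        duration_ms = -5, amplitude_uv = 1)
  expect_error(microstate_script(bad, tm), "positive")
})
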