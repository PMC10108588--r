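# greedy matching of recovered templates to truth by |spatial correlation|
match_templates <- function(recovered, truth) {
  r <- abs(painstates:::map_correlation(recovered, truth))
  out <- numeric(nrow(truth))
  used <- logical(nrow(recovered))
  for (j in seq_len(nrow(truth))) {
    free <- which(!used)
    i <- free[which.max(r[free, j])]
    used[i] <- TRUE
    out[j] <- r[i, j]
  }
  out
}

test_that("AAHC recovers planted clusters and degenerates gracefully", {
  truth <- fixed_templates(3, n_channels = 12, seed = 61)
  painstates:::with_seed(62, {
    maps <- truth[rep(1:3, each = 40), ] + matrix(rnorm(120 * 12, sd = 0.2),
                                                  120)
  })
  set <- cluster_microstates(maps, 3)
  expect_equal(set$k, 3)
  expect_true(all(match_templates(set$templates, truth) > 0.95))
  # unit GFP, average-referenced templates
  expect_lt(max(abs(rowMeans(set$templates))), 1e-9)
  expect_equal(unname(apply(set$templates, 1, gfp)), rep(1, 3),
               tolerance = 1e-9)
  # k = number of maps: every map its own template
  few <- truth + 0
  set_all <- cluster_microstates(few, 3)
  expect_equal(set_all$k, 3)
  # determinism on a duplicated map set
  s1 <- cluster_microstates(maps, 4)
  s2 <- cluster_microstates(maps, 4)
  expect_identical(s1$templates, s2$templates)
  expect_error(cluster_microstates(truth, 5), "exceeds")
})

test_that("training explained variance is non-decreasing in k", {
  truth <- fixed_templates(4, n_channels = 12, seed = 63)
  painstates:::with_seed(64, {
    maps <- truth[rep(1:4, each = 25), ] + matrix(rnorm(100 * 12, sd = 0.4),
                                                  100)
  })
  pool <- painstates:::prepare_pool(maps)
  fits <- painstates:::aahc(pool$maps, pool$w, k_keep = 2:8)
  ev <- vapply(2:8, function(k) {
    tm <- fits[[as.character(k)]]
    r <- painstates:::map_correlation(pool$maps, tm)
    best <- apply(pmax(r, 0), 1, max)
    sum((pool$w * best)^2) / sum(pool$w^2)
  }, 0)
  expect_true(all(diff(ev) > -1e-6))
})

test_that("split-half cross-validation finds the scripted k and flat nulls", {
  tm <- fixed_templates(3)
  sc <- small_script(tm, snr = 10, jitter_sd_ms = 5,
                     onsets = c(100, 400, 700), durations = c(200, 200, 200))
  coh <- generate_erp_cohort(cohort_spec(12, list(sc, sc), fs_hz = 125,
                                         seed = 65))
  tcts <- lapply(coh$epochs, tct, window_ms = c(-200, 1000), n_iter = 200,
                 seed = 66)
  sel <- select_k(coh$epochs, tcts, k_range = 2:6, n_iter = 20, seed = 67)
  expect_equal(sel$k_star, 3)
  # deterministic given the seed
  sel2 <- select_k(coh$epochs, tcts, k_range = 2:6, n_iter = 20, seed = 67)
  expect_identical(sel$curve, sel2$curve)
  # pure-noise cohort: flat curve, k* at the bottom of the range
  null_sc <- microstate_script(
    tibble::tibble(template_id = "M1", onset_ms = 100, duration_ms = 100,
                   amplitude_uv = 0), tm[1, , drop = FALSE], snr = 5)
  noise <- generate_erp_cohort(cohort_spec(12, list(null_sc, null_sc),
                                           fs_hz = 125, seed = 68))
  # no consistent topography exists; force pooling over the whole window
  fake_tct <- lapply(noise$epochs, function(es) {
    r <- tct(es, c(-200, 1000), n_iter = 20, seed = 69)
    r$significant <- rep(TRUE, length(r$significant))
    r
  })
  seln <- select_k(noise$epochs, fake_tct, k_range = 2:6, n_iter = 10,
                   seed = 70)
  # no elbow: the noise curve has no sharp gain followed by a collapse --
  # every gain is small and the explained-variance plateau stays far below
  # the structured cohort's
  expect_true(all(seln$curve$gain[-1] < 0.06))
  expect_lt(max(seln$curve$mean_ev), 0.6)
  expect_gt(sel$curve$mean_ev[sel$curve$k == 3], 0.8)
})

test_that("back-fitting returns exact activations in engineered cases", {
  all3 <- fixed_templates(3, n_channels = 12, seed = 71)
  tm <- all3[1:2, ]
  set <- cluster_microstates(tm, 2)
  # average equal to (a scaled copy of) template 1 at all timepoints
  avg <- 3 * set$templates[1, ] %o% rep(1, 10)
  s <- fit_microstates(avg, set, times_ms = seq(0, 90, 10))
  expect_equal(unname(s$c[1, ]), rep(1, 10), tolerance = 1e-9)
  expect_equal(s$explained_variance, 1, tolerance = 1e-9)
  # average orthogonal to every template explains nothing
  ortho <- all3[3, ]
  s2 <- fit_microstates(ortho %o% rep(1, 5), set, seq(0, 40, 10))
  expect_lt(s2$explained_variance, 1e-9)
  # zero-GFP timepoints are masked
  avg[, 4] <- 0
  s3 <- fit_microstates(avg, set, seq(0, 90, 10))
  expect_true(all(is.na(s3$c[, 4])))
})

test_that("scripted activations peak inside their scripted intervals", {
  tm <- fixed_templates(2)
  coh <- small_cohort(n = 12, snr = 10, fs = 250, seed = 72)
  tmn <- tm
  colnames(tmn) <- default_montage()
  set <- cluster_microstates(tmn, 2)
  s <- fit_microstates(coh$epochs$group1, set)
  peaks <- s$times_ms[apply(s$c, 1, which.max)]
  # match set templates back to generator templates
  ord <- apply(abs(painstates:::map_correlation(set$templates, tm)), 2,
               which.max)
  expect_true(peaks[ord[1]] >= 100 && peaks[ord[1]] < 300)
  expect_true(peaks[ord[2]] >= 500 && peaks[ord[2]] < 700)
})

test_that("activation significance flags scripted periods and not nulls", {
  tm <- fixed_templates(2)
  coh <- small_cohort(n = 15, snr = 10, fs = 250, seed = 73)
  es <- coh$epochs$group1
  tmn <- tm
  colnames(tmn) <- default_montage()
  set <- cluster_microstates(tmn, 2)
  bp <- baseline_map_pool(es, c(-500, 0))
  s <- fit_microstates(es, set)
  s <- activation_significance(s, es, bp, n_iter = 400, seed = 74)
  ord <- apply(abs(painstates:::map_correlation(set$templates, tm)), 2,
               which.max)
  act1 <- s$times_ms[s$active[ord[1], ]]
  expect_gt(length(act1), 0)
  expect_true(any(act1 >= 100 & act1 < 300))
  # a template never scripted: no active runs
  tm3 <- rbind(set$templates, fixed_templates(3, seed = 99)[3, ])
  set3 <- painstates:::new_microstate_set(tm3, es$montage, TRUE)
  s3 <- fit_microstates(es, set3)
  s3 <- activation_significance(s3, es, bp, n_iter = 400, seed = 75)
  expect_equal(sum(s3$active[3, ]), 0)
  # degenerate config: minimum run longer than the window
  expect_warning(
    activation_significance(s, es, bp, n_iter = 50, seed = 76,
                            min_run_ms = 1e6),
    "no activation")
})

test_that("event extraction applies the mean-duration merge rule", {
  times <- seq(0, 999, by = 1)
  k <- 1
  mk_series <- function(active_idx, mean_dur = NULL) {
    cmat <- matrix(0.5, 1, 1000, dimnames = list("MS1", NULL))
    s <- structure(list(c = cmat, gfp = rep(2, 1000), times_ms = times,
                        template_ids = "MS1", polarity_sensitive = TRUE,
                        explained_variance = 0.5),
                   class = "activation_series")
    act <- matrix(FALSE, 1, 1000, dimnames = list("MS1", NULL))
    act[1, active_idx] <- TRUE
    s$active <- act
    s
  }
  # single run [100, 300): one event, onset 100, duration 200
  s <- mk_series(101:300)
  ev <- extract_events(s)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_ms, 100)
  expect_equal(ev$duration_ms, 200)
  expect_equal(ev$power_uvms, sum(rep(2 * 0.5, 200)) * 1)
  # runs [100,200) and [600,700), forced mean duration 100: gap 400 > 100
  s2 <- mk_series(c(101:200, 601:700))
  ev2 <- extract_events(s2, mean_durations = c(MS1 = 100))
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$occurrence, c(1L, 2L))
  # runs [100,200) and [250,350) with mean duration 150: gap 50 <= 150
  s3 <- mk_series(c(101:200, 251:350))
  ev3 <- extract_events(s3, mean_durations = c(MS1 = 150))
  expect_equal(nrow(ev3), 1)
  expect_equal(ev3$onset_ms, 100)
  # extraction is deterministic given masks and series
  expect_identical(extract_events(s3, c(MS1 = 150)),
                   extract_events(s3, c(MS1 = 150)))
})

test_that("total field power equals the mean of per-timepoint GFPs", {
  times <- seq(-500, 999, by = 2)
  zero <- matrix(0, 6, length(times))
  expect_equal(total_field_power(zero, times), 0)
  # constant-GFP average built by construction
  tm <- fixed_templates(1, n_channels = 6, seed = 81)
  avg <- 3.7 * tm[1, ] %o% rep(1, length(times))
  expect_equal(total_field_power(avg, times), 3.7, tolerance = 1e-12)
  # brute force on an arbitrary average
  set.seed(82)
  avg2 <- matrix(rnorm(6 * length(times)), 6)
  idx <- times >= 0 & times < 1000
  brute <- mean(apply(avg2[, idx], 2, function(v) sqrt(mean((v - mean(v))^2))))
  expect_equal(total_field_power(avg2, times), brute, tolerance = 1e-12)
  expect_error(total_field_power(avg2, times, c(2000, 3000)), "no samples")
})

test_that("pooling collects exactly the consistent grand-average maps", {
  tm <- fixed_templates(2)
  coh <- small_cohort(n = 8, snr = 10, fs = 125, seed = 83)
  tcts <- lapply(coh$epochs, tct, window_ms = c(-200, 1000), n_iter = 100,
                 seed = 84)
  pool <- pool_consistent_maps(coh$epochs, tcts)
  expect_equal(nrow(pool$maps),
               sum(vapply(tcts, function(r) sum(r$significant), 0L)))
  expect_lt(max(abs(rowMeans(pool$maps))), 1e-9)
  # pooled maps come only from consistent latencies
  expect_true(all(pool$info$time_ms %in%
                    c(tcts[[1]]$times_ms[tcts[[1]]$significant],
                      tcts[[2]]$times_ms[tcts[[2]]$significant])))
  # no consistency anywhere: error
  none <- lapply(tcts, function(r) {
    r$significant <- rep(FALSE, length(r$significant)); r
  })
  expect_error(pool_consistent_maps(coh$epochs, none), "no topographically")
})
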