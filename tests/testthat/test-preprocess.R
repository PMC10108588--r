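# FFT amplitude of a single frequency component
fft_amp <- function(x, fs, f) {
  n <- length(x)
  k <- round(f * n / fs)
  2 * Mod(fft(x))[k + 1] / n
}

test_that("band-pass passes 10 Hz nearly untouched and the notch kills 50 Hz", {
  fs <- 500
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass_notch(x10, fs)
  mid <- seq(fs, length(t) - fs)            # skip edge transients
  expect_gt(fft_amp(y10[mid], fs, 10) / fft_amp(x10[mid], fs, 10), 0.95)
  # zero phase: peak cross-correlation at zero lag
  cc <- ccf(y10[mid], x10[mid], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  x50 <- sin(2 * pi * 50 * t)
  y50 <- bandpass_notch(x50, fs)
  expect_lt(fft_amp(y50[mid], fs, 50) / fft_amp(x50[mid], fs, 50), 0.10)
  expect_equal(bandpass_notch(rep(0, 1000), fs), rep(0, 1000))
  expect_error(bandpass_notch(c(1, NA, 3), fs), "non-finite")
  expect_error(bandpass_notch(rnorm(100), 60), "filter edge")
})

test_that("filtering is linear", {
  fs <- 500
  set.seed(21)
  x <- rnorm(2000); y <- rnorm(2000)
  lhs <- bandpass_notch(2.5 * x - 1.2 * y, fs)
  rhs <- 2.5 * bandpass_notch(x, fs) - 1.2 * bandpass_notch(y, fs)
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("common-average re-referencing zeroes time-slices and is idempotent", {
  set.seed(22)
  m <- matrix(rnorm(8 * 100), 8)
  shifted <- m + 3.7                          # constant reference offset
  r1 <- rereference_common_average(m)
  r2 <- rereference_common_average(shifted)
  expect_equal(r1, r2, tolerance = 1e-12)     # offset removed exactly
  expect_equal(max(abs(colMeans(r1))), 0, tolerance = 1e-12)
  expect_equal(rereference_common_average(r1), r1, tolerance = 1e-12)
  # GFP is reference-independent: same GFP under any prior reference
  expect_equal(painstates:::gfp_columns(r1),
               painstates:::gfp_columns(m), tolerance = 1e-9)
  expect_error(rereference_common_average(matrix(1, 1, 10)), "2 channels")
})

test_that("epoch extraction gets sample counts, alignment and bounds right", {
  x <- matrix(seq_len(2 * 5000), nrow = 2)
  ep <- epoch_data(x, fs_hz = 1000, trigger_sample = 2000)
  expect_equal(ncol(ep$data), 1500)
  expect_equal(which(ep$times_ms == 0), 501)  # 500 samples precede t = 0
  expect_equal(ep$data[1, 501], x[1, 2000])   # t = 0 is the trigger sample
  ep2 <- epoch_data(matrix(rnorm(8000), 2), fs_hz = 2000,
                    trigger_sample = 2000, window_ms = c(-500, 1000))
  expect_equal(ncol(ep2$data), 3000)
  expect_error(epoch_data(x, 1000, trigger_sample = 10), "edge")
  expect_error(epoch_data(x, 1000, 2000, window_ms = c(100, 50)), "exceed")
  # round trip: epochs of consecutive triggers tile the recording
  trg <- c(1000, 2500)
  eps <- lapply(trg, function(tr) epoch_data(x, 1000, tr, c(0, 1500))$data)
  expect_equal(cbind(eps[[1]], eps[[2]]), x[, 1000:3999, drop = FALSE])
})

test_that("spherical-spline interpolation reconstructs smooth maps", {
  mont <- default_montage()
  pos <- montage_1020(mont)
  set.seed(23)
  # smooth topography: rotating linear field over the sphere (degree-1
  # harmonics with time-varying coefficients, so every channel has a
  # nontrivial time course)
  nt <- 20
  tt <- seq_len(nt) / nt * 2 * pi
  D <- rbind(1.3 * sin(tt), -0.7 * cos(tt), 2.1 * sin(2 * tt))
  truth <- as.matrix(pos[, c("x", "y", "z")]) %*% D   # 18 x nt
  data <- array(0, c(1, 18, nt))
  data[1, , ] <- truth + rnorm(18 * nt, sd = 0.01)
  es <- epoch_set(data, fs_hz = 100, times_ms = seq(0, 190, by = 10),
                  montage = mont)
  es2 <- interpolate_channels(es, "Cz")
  i <- match("Cz", mont)
  expect_gt(cor(es2$data[1, i, ], data[1, i, ]), 0.9)
  expect_equal(es2$data[1, -i, ], data[1, -i, ])   # good channels untouched
  # no bad channels: identity
  expect_identical(interpolate_channels(es, character(0)), es)
  # constant map: spline reproduces constants
  cdata <- array(5, c(1, 18, 2))
  esc <- epoch_set(cdata, 100, c(0, 10), mont)
  esc2 <- interpolate_channels(esc, "O1")
  expect_equal(esc2$data[1, match("O1", mont), ], c(5, 5), tolerance = 1e-6)
  expect_error(interpolate_channels(es, mont[1:5]), "cap")
})

test_that("montage positions lie on the unit sphere", {
  pos <- montage_1020()
  expect_equal(nrow(pos), 18)
  r <- unname(sqrt(pos$x^2 + pos$y^2 + pos$z^2))
  expect_equal(r, rep(1, 18), tolerance = 1e-12)
  expect_error(montage_1020("Nose"), "no idealized position")
})
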