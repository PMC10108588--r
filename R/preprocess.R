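#' Zero-phase band-pass and notch filtering
#'
#' Conditions continuous EEG with a second-order Butterworth band-pass
#' (default 1-30 Hz) followed by a second-order Butterworth band-stop notch
#' (default 48-52 Hz, mains interference). Both filters are applied
#' bidirectionally (forward-backward, [signal::filtfilt()]), giving zero
#' phase shift and an effective fourth-order magnitude response.
#'
#' @param x Numeric vector (one channel) or channels x time matrix.
#' @param fs_hz Sampling rate in Hz; must exceed twice the highest filter
#'   edge (> 104 Hz with the default notch).
#' @param band Band-pass edges in Hz, length 2.
#' @param notch Band-stop edges in Hz, length 2, or `NULL` to skip.
#' @return Filtered data, same shape as `x`.
#' @export
bandpass_notch <- function(x, fs_hz, band = c(1, 30), notch = c(48, 52)) {
  if (!all(is.finite(x))) abort("input contains non-finite samples")
  hi <- max(band, notch)
  if (fs_hz <= 2 * hi) {
    abort(sprintf("fs = %g Hz cannot represent the %g Hz filter edge", fs_hz, hi))
  }
  nyq <- fs_hz / 2
  bp <- signal::butter(2, band / nyq, type = "pass")
  filt1 <- function(v) {
    v <- signal::filtfilt(bp, v)
    if (!is.null(notch)) {
      bs <- signal::butter(2, notch / nyq, type = "stop")
      v <- signal::filtfilt(bs, v)
    }
    v
  }
  if (is.matrix(x)) t(apply(x, 1, filt1)) else filt1(x)
}

#' Re-reference to the common average
#'
#' Expresses every channel relative to the instantaneous mean over all
#' channels, so each time-slice sums to zero. The operation is idempotent
#' and makes subsequent topographic measures reference-independent.
#'
#' @param x An [epoch_set()] or a channels x time matrix.
#' @return Same type as the input, common-average referenced.
#' @export
rereference_common_average <- function(x) {
  UseMethod("rereference_common_average")
}

#' @export
rereference_common_average.matrix <- function(x) {
  if (nrow(x) < 2) abort("common average needs at least 2 channels")
  sweep(x, 2, colMeans(x))
}

#' @export
rereference_common_average.epoch_set <- function(x) {
  if (dim(x$data)[2] < 2) abort("common average needs at least 2 channels")
  mu <- apply(x$data, c(1, 3), mean)          # subject x time
  d <- x$data - aperm(
    array(mu, c(dim(mu), dim(x$data)[2])), c(1, 3, 2))
  epoch_set(d, x$fs_hz, x$times_ms, x$montage, "common_average",
            x$subject_ids, x$interpolated)
}

#' Extract a stimulus-locked epoch from a continuous recording
#'
#' Cuts the half-open window `[window_ms[1], window_ms[2])`, aligned so that
#' t = 0 falls exactly on the trigger sample. The sample count is
#' `round((end - start) * fs / 1000)`.
#'
#' @param x Channels x time matrix (or vector) of continuous data.
#' @param fs_hz Sampling rate in Hz.
#' @param trigger_sample 1-based sample index of the stimulus.
#' @param window_ms Window `(start, end)` in ms around the trigger; default
#'   500 ms before to 1000 ms after.
#' @return List with `data` (channels x samples), `times_ms`, `fs_hz`.
#' @export
#' @examples
#' x <- matrix(rnorm(4 * 3000), 4)
#' ep <- epoch_data(x, fs_hz = 1000, trigger_sample = 1000)
#' length(ep$times_ms) # 1500 samples
epoch_data <- function(x, fs_hz, trigger_sample, window_ms = c(-500, 1000)) {
  if (window_ms[2] <= window_ms[1]) abort("window end must exceed start")
  if (!(window_ms[1] <= 0 && window_ms[2] > 0)) {
    abort("epoch window must contain the trigger (t = 0)")
  }
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  dt <- 1000 / fs_hz
  off0 <- round(window_ms[1] * fs_hz / 1000)
  n <- round((window_ms[2] - window_ms[1]) * fs_hz / 1000)
  first <- trigger_sample + off0
  last <- first + n - 1
  if (first < 1 || last > ncol(x)) {
    abort("trigger too close to the recording edge for this window")
  }
  list(data = x[, first:last, drop = FALSE],
       times_ms = (off0 + seq_len(n) - 1) * dt,
       fs_hz = fs_hz)
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces channels that could not be recorded or denoised with
#' spherical-spline estimates from the remaining channels (Perrin-style
#' splines on the unit sphere, stiffness order `m`, truncated Legendre
#' expansion). Good channels are untouched. The estimate is linear in the
#' good-channel data, so one interpolation operator is computed and applied
#' to every subject and timepoint.
#'
#' @param es An [epoch_set()].
#' @param bad Character vector of channel names to reconstruct.
#' @param positions Electrode positions as from [montage_1020()]; must cover
#'   the full montage.
#' @param m Spline stiffness order (default 4).
#' @param n_terms Number of Legendre terms in the truncated expansion
#'   (default 7).
#' @param max_bad Maximum number of reconstructable channels (default 4,
#'   the most ever needed in practice for this montage).
#' @return The epoch set with `bad` channels replaced and recorded in
#'   `interpolated` for every subject.
#' @export
interpolate_channels <- function(es, bad, positions = montage_1020(es$montage),
                                 m = 4, n_terms = 7, max_bad = 4) {
  stopifnot(inherits(es, "epoch_set"))
  if (length(bad) == 0) return(es)
  if (length(bad) > max_bad) {
    abort(sprintf("%d bad channels exceeds the cap of %d", length(bad), max_bad))
  }
  if (!all(bad %in% es$montage)) abort("bad channel not in montage")
  if (!all(es$montage %in% positions$channel)) {
    abort("positions missing for some montage channels")
  }
  positions <- positions[match(es$montage, positions$channel), ]
  good <- setdiff(es$montage, bad)
  gi <- match(good, es$montage)
  bi <- match(bad, es$montage)
  op <- spline_operator(positions, gi, bi, m = m, n_terms = n_terms)
  d <- es$data
  for (s in seq_len(dim(d)[1])) {
    seg <- d[s, gi, , drop = TRUE]
    if (is.null(dim(seg))) seg <- matrix(seg, nrow = length(gi))
    d[s, bi, ] <- op %*% rbind(seg, 1)
  }
  epoch_set(d, es$fs_hz, es$times_ms, es$montage, es$reference,
            es$subject_ids,
            lapply(es$interpolated, function(ch) union(ch, bad)))
}

# Legendre polynomials P_1..P_n at x (vectorized over x); rows = order
legendre_terms <- function(x, n) {
  out <- matrix(0, n, length(x))
  pm2 <- rep(1, length(x))        # P_0
  pm1 <- x                        # P_1
  out[1, ] <- pm1
  if (n >= 2) {
    for (k in 2:n) {
      p <- ((2 * k - 1) * x * pm1 - (k - 1) * pm2) / k
      out[k, ] <- p
      pm2 <- pm1
      pm1 <- p
    }
  }
  out
}

# spherical spline kernel g(cos angle), truncated expansion
spline_g <- function(cosang, m, n_terms) {
  n <- seq_len(n_terms)
  w <- (2 * n + 1) / (n^m * (n + 1)^m)
  P <- legendre_terms(pmin(pmax(cosang, -1), 1), n_terms)
  as.vector(w %*% P) / (4 * pi)
}

# linear operator mapping rbind(good-channel data, 1) -> bad-channel estimates
spline_operator <- function(positions, good_idx, bad_idx, m = 4, n_terms = 7) {
  xyz <- as.matrix(positions[, c("x", "y", "z")])
  xyz <- xyz / sqrt(rowSums(xyz^2))
  cosang <- tcrossprod(xyz)
  k <- length(good_idx)
  G <- matrix(spline_g(cosang[good_idx, good_idx], m, n_terms), k, k)
  M <- rbind(cbind(G, 1), c(rep(1, k), 0))
  Gb <- matrix(spline_g(cosang[bad_idx, good_idx, drop = FALSE], m, n_terms),
               length(bad_idx), k)
  # v_bad = [Gb 1] %*% solve(M, [v_good; 0]); the trailing column multiplies
  # the appended row of ones (the constant term's zero right-hand side)
  op <- cbind(Gb, 1) %*% solve(M)
  op[, ncol(op)] <- 0
  op
}

#' Artifact-denoising hook
#'
#' Independent-component artifact removal is a manual, toolbox-driven step
#' and is outside this package's scope; the pipeline accepts pre-cleaned
#' data. This identity hook marks where a user-supplied denoiser slots in.
#'
#' @param es An [epoch_set()] (or any data object).
#' @param fun Optional function applied to `es`; default identity.
#' @return `fun(es)`.
#' @export
denoise_hook <- function(es, fun = identity) fun(es)
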