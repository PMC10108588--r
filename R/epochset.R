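#' Construct a set of stimulus-locked EEG epochs
#'
#' An `epoch_set` holds one epoch per subject as a subjects x channels x time
#' array (microvolts), with a uniform time axis in milliseconds relative to
#' the stimulus (t = 0 is the release of the heel lance), an ordered 10/20
#' montage, and the current reference state.
#'
#' @param data Numeric array `[subject, channel, time]`, or a list of
#'   channels x time matrices (one per subject).
#' @param fs_hz Sampling rate in Hz.
#' @param times_ms Time axis in ms; must be uniform with step `1000 / fs_hz`.
#' @param montage Character vector of channel names, length = #channels.
#' @param reference `"original"` or `"common_average"`.
#' @param subject_ids Optional character vector of subject identifiers.
#' @param interpolated Optional list (per subject) of interpolated channel
#'   names.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs_hz, times_ms, montage,
                      reference = c("original", "common_average"),
                      subject_ids = NULL, interpolated = NULL) {
  reference <- match.arg(reference)
  if (is.list(data)) {
    data <- simplify2array(data)       # channels x time x subject
    data <- aperm(data, c(3, 1, 2))
  }
  stopifnot(is.array(data), length(dim(data)) == 3)
  n_sub <- dim(data)[1]
  if (dim(data)[2] != length(montage)) {
    abort("channel dimension does not match montage length")
  }
  if (dim(data)[3] != length(times_ms)) {
    abort("time dimension does not match time axis length")
  }
  dt <- 1000 / fs_hz
  steps <- diff(times_ms)
  if (length(steps) && (any(steps <= 0) || any(abs(steps - dt) > 1e-6))) {
    abort("time axis must be strictly increasing with step 1000/fs_hz")
  }
  if (reference == "common_average") {
    mu <- apply(data, c(1, 3), mean)
    if (max(abs(mu)) > 1e-6) {
      abort("data declared common-average referenced but time-slices do not sum to 0")
    }
  }
  if (is.null(subject_ids)) subject_ids <- sprintf("S%02d", seq_len(n_sub))
  if (is.null(interpolated)) interpolated <- rep(list(character()), n_sub)
  structure(
    list(data = data, fs_hz = fs_hz, times_ms = times_ms,
         montage = montage, reference = reference,
         subject_ids = subject_ids, interpolated = interpolated),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d subjects x %d channels x %d samples @ %g Hz, %s reference\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs_hz,
    gsub("_", " ", x$reference)))
  cat(sprintf("  window [%g, %g) ms\n", x$times_ms[1],
              x$times_ms[length(x$times_ms)] + 1000 / x$fs_hz))
  invisible(x)
}

#' Tidy an epoch set into a long tibble
#'
#' @param x An `epoch_set`.
#' @param ... Unused.
#' @return A tibble with columns `subject_id`, `channel`, `time_ms`,
#'   `amplitude_uv`.
#' @export
tidy.epoch_set <- function(x, ...) {
  d <- x$data
  tibble::tibble(
    subject_id = rep(x$subject_ids, times = dim(d)[2] * dim(d)[3]),
    channel = rep(rep(x$montage, each = dim(d)[1]), times = dim(d)[3]),
    time_ms = rep(x$times_ms, each = dim(d)[1] * dim(d)[2]),
    amplitude_uv = as.vector(d)
  )
}

#' @export
glance.epoch_set <- function(x, ...) {
  tibble::tibble(
    n_subjects = dim(x$data)[1], n_channels = dim(x$data)[2],
    n_samples = dim(x$data)[3], fs_hz = x$fs_hz,
    window_start_ms = x$times_ms[1],
    window_end_ms = x$times_ms[length(x$times_ms)] + 1000 / x$fs_hz,
    reference = x$reference
  )
}

# channels x time grand average across subjects
grand_average <- function(es, subjects = NULL) {
  stopifnot(inherits(es, "epoch_set"))
  d <- es$data
  if (!is.null(subjects)) d <- d[subjects, , , drop = FALSE]
  out <- apply(d, c(2, 3), mean)
  dimnames(out) <- list(es$montage, NULL)
  out
}

# subjects kept as a flat matrix: subjects x (channels*time), plus helpers to
# reshape -- used by permutation loops where colMeans beats apply()
flatten_epochs <- function(es) {
  d <- es$data
  dim(d) <- c(dim(d)[1], dim(d)[2] * dim(d)[3])
  d
}

unflatten_map <- function(v, n_channels) {
  matrix(v, nrow = n_channels)
}

# restrict an epoch_set to a time window [start, end) in ms
window_epochs <- function(es, window_ms) {
  idx <- which(es$times_ms >= window_ms[1] & es$times_ms < window_ms[2])
  if (!length(idx)) abort("window contains no samples")
  epoch_set(es$data[, , idx, drop = FALSE], es$fs_hz, es$times_ms[idx],
            es$montage, es$reference, es$subject_ids, es$interpolated)
}
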