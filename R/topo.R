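#' Global field power of a scalp map
#'
#' The global field power (GFP) is the population standard deviation of the
#' potential across all electrodes at one timepoint. It is a
#' reference-independent descriptor of the momentary strength of the scalp
#' field: adding a constant to every channel (changing the reference) leaves
#' it unchanged, and scaling the map by `c > 0` scales the GFP by `c`.
#'
#' @param map Numeric vector of per-channel potentials (microvolts).
#' @return Non-negative scalar GFP in the units of `map`.
#' @export
#' @examples
#' gfp(c(1, -1, 1, -1)) # 1
#' gfp(rep(3.2, 8))     # 0: constant maps carry no field
gfp <- function(map) {
  if (length(map) < 2) abort("GFP needs at least 2 channels")
  if (anyNA(map)) abort("GFP input contains missing values")
  sqrt(mean((map - mean(map))^2))
}

# GFP of every column of a channels x time matrix (population SD)
gfp_columns <- function(mat) {
  mu <- colMeans(mat)
  sqrt(colMeans(mat^2) - mu^2)
}

# scale every column of an average-referenced channels x time matrix to unit
# GFP; zero-GFP columns come back as zero columns (flagged by attribute)
normalize_columns <- function(mat) {
  g <- gfp_columns(mat)
  ok <- g > 0
  mat[, ok] <- sweep(mat[, ok, drop = FALSE], 2, g[ok], "/")
  mat[, !ok] <- 0
  attr(mat, "zero_gfp") <- !ok
  mat
}

#' Topographic dissimilarity index between two scalp maps
#'
#' The dissimilarity index (DISS) is the root-mean-square difference between
#' two average-referenced maps after each is normalized to unit global field
#' power. It ranges from 0 (identical field configuration, regardless of
#' strength) to 2 (identical configuration with reversed polarity), and is
#' invariant to positive rescaling of either map. It satisfies
#' `DISS^2 = 2 * (1 - r)` where `r` is the spatial Pearson correlation of the
#' average-referenced maps.
#'
#' @param u,v Numeric vectors of per-channel potentials over the same
#'   montage; each must have nonzero GFP.
#' @return Scalar in `[0, 2]`.
#' @export
#' @examples
#' u <- c(1, 0, -1, 0)
#' diss(u, u)   # 0
#' diss(u, -u)  # 2
#' diss(u, c(0, 1, 0, -1)) # sqrt(2): orthogonal configurations
diss <- function(u, v) {
  if (length(u) != length(v)) abort("maps must share a montage")
  u <- u - mean(u)
  v <- v - mean(v)
  gu <- gfp(u)
  gv <- gfp(v)
  if (gu == 0 || gv == 0) abort("DISS is undefined for zero-GFP maps")
  sqrt(mean((u / gu - v / gv)^2))
}

# DISS between paired columns of two average-referenced channels x time
# matrices; columns where either side has zero GFP return NA
diss_columns <- function(a, b) {
  an <- normalize_columns(a)
  bn <- normalize_columns(b)
  out <- sqrt(colMeans((an - bn)^2))
  out[attr(an, "zero_gfp") | attr(bn, "zero_gfp")] <- NA_real_
  out
}

#' Keep only significance runs at least a minimum duration long
#'
#' Randomization tests in this package control for multiple comparisons over
#' time by discarding significant timepoints that are not part of a
#' continuous run covering at least a fixed fraction (by default 5%) of the
#' tested window. This helper turns a per-timepoint logical significance
#' vector into the surviving segments.
#'
#' @param significant Logical vector over timepoints (NA treated as FALSE).
#' @param times_ms Numeric vector of timepoint latencies (ms), uniform step.
#' @param min_run_ms Minimum run duration in ms; runs shorter than this are
#'   dropped. A run of `k` samples covers `k * dt` ms (half-open segments).
#' @return A list with `keep`, the filtered logical vector, and `segments`,
#'   a tibble of surviving `[start_ms, end_ms)` segments with durations.
#' @export
run_length_filter <- function(significant, times_ms, min_run_ms) {
  stopifnot(length(significant) == length(times_ms))
  significant[is.na(significant)] <- FALSE
  if (length(times_ms) < 2) {
    keep <- significant & FALSE
    return(list(keep = keep, segments = empty_segments()))
  }
  dt <- times_ms[2] - times_ms[1]
  r <- rle(as.logical(significant))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- logical(length(significant))
  seg <- list()
  for (i in seq_along(r$lengths)) {
    if (!r$values[i]) next
    dur <- r$lengths[i] * dt
    if (dur >= min_run_ms) {
      keep[starts[i]:ends[i]] <- TRUE
      seg[[length(seg) + 1]] <- tibble::tibble(
        start_ms = times_ms[starts[i]],
        end_ms = times_ms[ends[i]] + dt,
        duration_ms = dur
      )
    }
  }
  segments <- if (length(seg)) dplyr::bind_rows(seg) else empty_segments()
  list(keep = keep, segments = segments)
}

empty_segments <- function() {
  tibble::tibble(start_ms = numeric(), end_ms = numeric(),
                 duration_ms = numeric())
}

# right-tailed randomization threshold with the +1 correction: exceeding
# the k-th largest of n null values (k = floor(alpha (n+1))) happens with
# probability k/(n+1) <= alpha under exchangeability
null_threshold <- function(null_values, alpha) {
  n <- length(null_values)
  k <- floor(alpha * (n + 1))
  if (k < 1) return(Inf)
  sort(null_values, decreasing = TRUE)[k]
}
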