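#' Idealized 10/20 electrode positions on the unit sphere
#'
#' Returns idealized spherical coordinates for channels of the international
#' 10/20 placement system, built geometrically: the vertex at Cz, midline and
#' coronal arcs at 20% (45 degree) steps, the circumferential ring at 90
#' degrees inclination in 10% (18 degree) compass steps, intermediate
#' positions as normalized great-circle midpoints, and the inferior
#' temporo-parietal pair (TP9/TP10) 18 degrees below the ring. These are
#' idealized spherical positions, not digitized locations.
#'
#' @param channels Character vector of channel names; default is the
#'   18-channel neonatal recording montage used throughout the package
#'   (visual, auditory, association and somatosensory coverage, with Fz as
#'   the recording reference and therefore not part of the default set).
#' @return A tibble with columns `channel`, `x` (towards the right ear),
#'   `y` (towards the nasion), `z` (towards the vertex); rows in the order
#'   of `channels`.
#' @export
#' @examples
#' montage_1020()
#' montage_1020(c("Cz", "C3", "C4"))
montage_1020 <- function(channels = default_montage()) {
  pos <- montage_positions()
  missing <- setdiff(channels, pos$channel)
  if (length(missing) > 0) {
    abort(paste0("no idealized position for channel(s): ",
                 paste(missing, collapse = ", ")))
  }
  pos[match(channels, pos$channel), , drop = FALSE]
}

#' Default 18-channel montage
#'
#' The scalp channels of the neonatal recording layout: O1/O2 (visual),
#' T7/T8 (auditory), F7/F3/F4/F8/P7/P8/TP9/TP10 (association) and
#' C3/Cz/C4/CP3/CPz/CP4 (somatosensory).
#'
#' @return Character vector of 18 channel names.
#' @export
default_montage <- function() {
  c("F7", "F3", "F4", "F8",
    "T7", "C3", "Cz", "C4", "T8",
    "TP9", "CP3", "CPz", "CP4", "TP10",
    "P7", "P8", "O1", "O2")
}

# unit-sphere point from inclination (deg from vertex) and compass azimuth
# (deg, 0 = nasion, clockwise towards the right ear)
sph_point <- function(incl, compass) {
  ti <- incl * pi / 180
  tc <- compass * pi / 180
  c(x = sin(ti) * sin(tc), y = sin(ti) * cos(tc), z = cos(ti))
}

great_circle_mid <- function(a, b) {
  m <- a + b
  m / sqrt(sum(m^2))
}

montage_positions <- function() {
  p <- list(
    Cz  = sph_point(0, 0),
    Fz  = sph_point(45, 0),
    Pz  = sph_point(45, 180),
    C3  = sph_point(45, 270),
    C4  = sph_point(45, 90),
    Fpz = sph_point(90, 0),
    Fp2 = sph_point(90, 18),
    F8  = sph_point(90, 54),
    T8  = sph_point(90, 90),
    P8  = sph_point(90, 126),
    O2  = sph_point(90, 162),
    Oz  = sph_point(90, 180),
    O1  = sph_point(90, 198),
    P7  = sph_point(90, 234),
    T7  = sph_point(90, 270),
    F7  = sph_point(90, 306),
    Fp1 = sph_point(90, 342),
    TP9  = sph_point(108, 252),
    TP10 = sph_point(108, 108)
  )
  p$F3 <- great_circle_mid(p$Fz, p$F7)
  p$F4 <- great_circle_mid(p$Fz, p$F8)
  p$P3 <- great_circle_mid(p$Pz, p$P7)
  p$P4 <- great_circle_mid(p$Pz, p$P8)
  p$CPz <- great_circle_mid(p$Cz, p$Pz)
  p$CP3 <- great_circle_mid(p$C3, p$P3)
  p$CP4 <- great_circle_mid(p$C4, p$P4)
  p$FCz <- great_circle_mid(p$Cz, p$Fz)
  m <- do.call(rbind, p)
  tibble::tibble(channel = rownames(m), x = m[, 1], y = m[, 2], z = m[, 3])
}

# pairwise great-circle (angular) distance matrix, radians
montage_angles <- function(positions) {
  xyz <- as.matrix(positions[, c("x", "y", "z")])
  cosang <- tcrossprod(xyz)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  acos(cosang)
}
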