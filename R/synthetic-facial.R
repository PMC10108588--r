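#' The seven NFCS facial actions and standard constellations
#'
#' The Neonatal Facial Coding System codes seven discrete facial actions
#' second by second. Three constellations are in common use: the full
#' seven-action score (max 70 over a 10 s epoch), a three-action score used
#' with older infants (max 30), and the three actions shared with the
#' Premature Infant Pain Profile-Revised (max 30), on which the 9/30
#' clinical threshold is defined.
#'
#' @return `nfcs_actions()`: character vector of the 7 action names.
#'   `nfcs_constellation(which)`: the action names of one constellation.
#' @export
nfcs_actions <- function() {
  c("brow bulge", "eye squeeze", "nasolabial furrow", "open lips",
    "vertical stretch mouth", "horizontal stretch mouth", "taut tongue")
}

#' @param which One of `"nfcs7"`, `"nfcs3"`, `"nfcs_p3"`.
#' @rdname nfcs_actions
#' @export
nfcs_constellation <- function(which = c("nfcs_p3", "nfcs3", "nfcs7")) {
  which <- match.arg(which)
  switch(which,
    nfcs7 = nfcs_actions(),
    nfcs3 = c("eye squeeze", "vertical stretch mouth",
              "horizontal stretch mouth"),
    nfcs_p3 = c("brow bulge", "eye squeeze", "nasolabial furrow")
  )
}

#' Specify a synthetic facial-coding cohort
#'
#' Emulates second-by-second binary facial-action coding with
#' obstruction-driven missingness. Two groups differ in their per-second
#' action probabilities; with the defaults (0.8 vs 0.1) the pooled total
#' scores form the strongly bimodal distribution seen in neonatal cohorts,
#' with most subjects at the extremes of the scale.
#'
#' @param n_subjects_per_group Integer >= 1 per group.
#' @param p_action_per_second Length-2 list or vector: each element either a
#'   single probability applied to all 7 actions or a named/ordered
#'   7-vector, for groups 1 and 2 during the reactivity epoch.
#' @param baseline_p Per-second action probability during the baseline
#'   epoch (default 0.02; baseline facial activity is rare).
#' @param obstruction List: `bout_rate` (expected obstruction bouts per
#'   epoch, Poisson) and `bout_length_mean` (mean bout length in seconds,
#'   >= 1; 1 + Poisson(mean - 1)).
#' @param constancy_flags Probability that cry and body movements remain
#'   constant through an obstructed epoch (each drawn independently).
#' @param seed Integer seed.
#' @return An object of class `facial_sim_spec`.
#' @export
facial_sim_spec <- function(n_subjects_per_group,
                            p_action_per_second = c(0.8, 0.1),
                            baseline_p = 0.02,
                            obstruction = list(bout_rate = 0.3,
                                               bout_length_mean = 2),
                            constancy_flags = 0.8,
                            seed = 1L) {
  p <- lapply(1:2, function(g) {
    pg <- if (is.list(p_action_per_second)) p_action_per_second[[g]]
          else p_action_per_second[g]
    if (length(pg) == 1) pg <- rep(pg, 7)
    if (length(pg) != 7) abort("per-action probabilities must have length 1 or 7")
    if (any(pg < 0 | pg > 1)) abort("probabilities must lie in [0, 1]")
    pg
  })
  if (baseline_p < 0 || baseline_p > 1) abort("baseline_p must lie in [0, 1]")
  if (obstruction$bout_length_mean < 1) abort("bout lengths must be >= 1 s")
  if (constancy_flags < 0 || constancy_flags > 1) {
    abort("constancy_flags must lie in [0, 1]")
  }
  structure(list(n_subjects_per_group = as.integer(n_subjects_per_group),
                 p = p, baseline_p = baseline_p, obstruction = obstruction,
                 constancy_flags = constancy_flags, seed = as.integer(seed)),
            class = "facial_sim_spec")
}

#' Generate a synthetic facial-coding cohort with known totals
#'
#' Draws 7-action x 10-second binary coding matrices for a baseline and a
#' reactivity epoch per subject, overlays obstruction bouts (all actions
#' unobservable during obstructed seconds, reason code `"obstructed"`), and
#' attaches cry/body-movement constancy flags for the missing-data rules.
#'
#' @param spec A [facial_sim_spec()].
#' @return List with `coding`, a long tibble (`subject_id`, `group`,
#'   `epoch`, `action`, `second`, `value`, `missing_reason`,
#'   `cry_constant`, `body_constant`, `coder_override`), and
#'   `ground_truth`, the pre-obstruction per-subject constellation totals.
#' @export
generate_facial_cohort <- function(spec) {
  stopifnot(inherits(spec, "facial_sim_spec"))
  with_seed(spec$seed, {
    rows <- list()
    truths <- list()
    acts <- nfcs_actions()
    for (g in 1:2) {
      for (s in seq_len(spec$n_subjects_per_group)) {
        sid <- sprintf("G%dS%02d", g, s)
        for (ep in c("baseline", "reactivity")) {
          p <- if (ep == "baseline") rep(spec$baseline_p, 7) else spec$p[[g]]
          m <- matrix(rbinom(70, 1, rep(p, times = 10)), nrow = 7)
          obstructed <- obstruction_mask(spec$obstruction)
          cry <- runif(1) < spec$constancy_flags
          body <- runif(1) < spec$constancy_flags
          truths[[length(truths) + 1]] <- tibble::tibble(
            subject_id = sid, group = paste0("group", g), epoch = ep,
            constellation = c("nfcs7", "nfcs3", "nfcs_p3"),
            true_total = vapply(c("nfcs7", "nfcs3", "nfcs_p3"), function(cc) {
              sum(m[match(nfcs_constellation(cc), acts), ])
            }, 0)
          )
          value <- as.vector(m)
          reason <- rep(NA_character_, 70)
          if (any(obstructed)) {
            hit <- rep(obstructed, each = 7)
            value[hit] <- NA_integer_
            reason[hit] <- "obstructed"
          }
          rows[[length(rows) + 1]] <- tibble::tibble(
            subject_id = sid, group = paste0("group", g), epoch = ep,
            action = rep(acts, times = 10),
            second = rep(1:10, each = 7),
            value = value, missing_reason = reason,
            cry_constant = cry, body_constant = body,
            coder_override = FALSE
          )
        }
      }
    }
    list(coding = dplyr::bind_rows(rows),
         ground_truth = dplyr::bind_rows(truths))
  })
}

# logical mask over the 10 seconds of one epoch
obstruction_mask <- function(obstruction) {
  mask <- rep(FALSE, 10)
  n_bouts <- stats::rpois(1, obstruction$bout_rate)
  if (n_bouts > 0) {
    for (b in seq_len(n_bouts)) {
      start <- sample(1:10, 1)
      len <- 1 + stats::rpois(1, obstruction$bout_length_mean - 1)
      mask[start:min(10, start + len - 1)] <- TRUE
    }
  }
  mask
}
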