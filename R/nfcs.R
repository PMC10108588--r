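#' Sum an NFCS constellation over a fully observed coding table
#'
#' Totals the second-by-second binary codes of one constellation's actions
#' over each subject x epoch. The maximum is 70 for the seven-action
#' constellation and 30 for the three-action constellations. Cells must be
#' fully observed for the constellation's actions; run [handle_missing()]
#' first if the table contains missing codes.
#'
#' @param coding Long coding tibble as produced by
#'   [generate_facial_cohort()]: one row per `subject_id` x `epoch` x
#'   `action` x `second` with a binary (or missing) `value`.
#' @param constellation `"nfcs_p3"`, `"nfcs3"` or `"nfcs7"`.
#' @return Tibble with one row per subject x epoch: `subject_id`, `epoch`,
#'   `constellation`, `total`, `max_score` (and `group` if present).
#' @export
#' @examples
#' cohort <- generate_facial_cohort(facial_sim_spec(2, c(1, 0),
#'   obstruction = list(bout_rate = 0, bout_length_mean = 1)))
#' score_constellation(cohort$coding, "nfcs7")
score_constellation <- function(coding,
                                constellation = c("nfcs_p3", "nfcs3", "nfcs7")) {
  constellation <- match.arg(constellation)
  acts <- nfcs_constellation(constellation)
  sub <- dplyr::filter(coding, .data$action %in% acts)
  check_cells(sub)
  if (anyNA(sub$value)) {
    abort(paste("coding contains unresolved missing cells;",
                "apply handle_missing() before scoring"))
  }
  keys <- intersect(c("subject_id", "group", "epoch"), names(sub))
  cons <- constellation
  mx <- max_score(constellation)
  sub |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(total = sum(.data$value), .groups = "drop") |>
    dplyr::mutate(constellation = cons, max_score = mx)
}

max_score <- function(constellation) {
  10 * length(nfcs_constellation(constellation))
}

check_cells <- function(coding) {
  v <- coding$value
  if (!all(is.na(v) | v %in% c(0, 1))) {
    abort("coding cells must be 0, 1 or missing")
  }
  n <- dplyr::count(coding, .data$subject_id, .data$epoch, .data$action)
  if (any(n$n != 10)) abort("each action must have exactly 10 seconds of cells")
  invisible(TRUE)
}

#' Apply the NFCS missing-data management rules
#'
#' Applies, in order, the three conservative procedures for obstructed
#' facial-action codes:
#'
#' 1. *Facial symmetry* is a judgement the coder makes while coding (scoring
#'    the visible half of the face); any `symmetry_used` flag is passed
#'    through unchanged.
#' 2. *Constancy fill*, per action: if at least `min_coverage` (default
#'    60%) of that action's 10 seconds is codable, cry and body movements
#'    remained constant through the epoch, and the coder has no reason to
#'    believe facial activity changed (`coder_override` is FALSE), each
#'    missing cell is filled with the closest preceding observed value --
#'    or the closest following value, flagged, when the gap opens the epoch.
#' 3. *Proration*: where constancy does not apply but at least
#'    `min_coverage` of all cells across the constellation's actions is
#'    observed, the record is marked for proration: its total is the
#'    observed sum scaled by `total_cells / observed_cells` (capped at the
#'    constellation maximum).
#' 4. Otherwise the subject x epoch record is *excluded*.
#'
#' @param coding Long coding tibble (see [generate_facial_cohort()]).
#' @param constellation Constellation whose actions the coverage and
#'   proration computations run over.
#' @param min_coverage Minimum observed fraction (default 0.6) for both the
#'   per-action constancy screen and overall proration.
#' @return List with `coding` (constellation's actions only, constancy
#'   fills applied) and `flags`, one row per subject x epoch with
#'   `constancy_used`, `forward_filled` (a gap opened the epoch),
#'   `prorated`, `prorate_factor`, `excluded`, plus cell counts.
#' @export
handle_missing <- function(coding,
                           constellation = c("nfcs_p3", "nfcs3", "nfcs7"),
                           min_coverage = 0.6) {
  constellation <- match.arg(constellation)
  acts <- nfcs_constellation(constellation)
  sub <- dplyr::filter(coding, .data$action %in% acts)
  check_cells(sub)
  sub <- dplyr::arrange(sub, .data$subject_id, .data$epoch, .data$action,
                        .data$second)
  keys <- dplyr::distinct(sub, .data$subject_id, .data$epoch)
  out <- vector("list", nrow(keys))
  flags <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    rec <- dplyr::semi_join(sub, keys[i, ], by = c("subject_id", "epoch"))
    constant <- isTRUE(rec$cry_constant[1]) && isTRUE(rec$body_constant[1]) &&
      !isTRUE(rec$coder_override[1])
    constancy_used <- FALSE
    forward_filled <- FALSE
    if (constant && anyNA(rec$value)) {
      for (a in acts) {
        idx <- which(rec$action == a)
        v <- rec$value[idx]
        if (!anyNA(v)) next
        if (mean(!is.na(v)) >= min_coverage) {
          rec$value[idx] <- locf_fill(v)
          constancy_used <- TRUE
          if (is.na(v[1])) forward_filled <- TRUE
        }
      }
    }
    observed <- sum(!is.na(rec$value))
    total_cells <- nrow(rec)
    prorated <- FALSE
    excluded <- FALSE
    factor <- 1
    if (anyNA(rec$value)) {
      if (observed / total_cells >= min_coverage) {
        prorated <- TRUE
        factor <- total_cells / observed
      } else {
        excluded <- TRUE
      }
    }
    out[[i]] <- rec
    flags[[i]] <- tibble::tibble(
      subject_id = keys$subject_id[i], epoch = keys$epoch[i],
      symmetry_used = "symmetry_used" %in% names(rec) &&
        isTRUE(rec[["symmetry_used"]][1]),
      constancy_used = constancy_used, forward_filled = forward_filled,
      prorated = prorated, prorate_factor = factor, excluded = excluded,
      observed_cells = observed, total_cells = total_cells
    )
  }
  list(coding = dplyr::bind_rows(out), flags = dplyr::bind_rows(flags))
}

# fill NAs with the closest preceding observed value; a leading gap takes
# the closest following value
locf_fill <- function(v) {
  n <- length(v)
  last <- NA
  for (i in seq_len(n)) {
    if (is.na(v[i])) v[i] <- last else last <- v[i]
  }
  for (i in rev(seq_len(n))) {        # leading gap: nearest following value
    if (is.na(v[i])) v[i] <- last else last <- v[i]
  }
  v
}

#' Score an NFCS constellation with missing-data handling
#'
#' Convenience wrapper: runs [handle_missing()] and then totals each
#' subject x epoch, using the prorated total where proration applied and
#' `NA` for excluded records. Prorated totals are capped at the
#' constellation maximum (and flagged when the cap binds).
#'
#' @inheritParams handle_missing
#' @return Tibble with one row per subject x epoch: totals, max score and
#'   the provenance flags from [handle_missing()].
#' @export
score_nfcs <- function(coding,
                       constellation = c("nfcs_p3", "nfcs3", "nfcs7"),
                       min_coverage = 0.6) {
  constellation <- match.arg(constellation)
  h <- handle_missing(coding, constellation, min_coverage)
  mx <- max_score(constellation)
  keys <- intersect(c("subject_id", "group", "epoch"), names(h$coding))
  base <- h$coding |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(observed_sum = sum(.data$value, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::left_join(h$flags, by = c("subject_id", "epoch")) |>
    dplyr::mutate(
      total = dplyr::case_when(
        .data$excluded ~ NA_real_,
        .data$prorated ~ pmin(.data$observed_sum * .data$prorate_factor, mx),
        TRUE ~ .data$observed_sum
      ),
      capped = .data$prorated &
        .data$observed_sum * .data$prorate_factor > mx,
      constellation = constellation, max_score = mx
    )
  dplyr::select(base, dplyr::all_of(keys), "constellation", "total",
                "max_score", "symmetry_used", "constancy_used",
                "forward_filled", "prorated", "excluded", "capped")
}

#' Linearly rescale a seven-action total to the 0-30 range
#'
#' Puts NFCS-7 totals (0-70) on the 0-30 scale of the three-action
#' constellations for within-subject comparison: `total * 30 / 70`.
#'
#' @param total_0_to_70 Numeric vector of totals in `[0, 70]`.
#' @return The totals scaled to `[0, 30]`.
#' @export
#' @examples
#' scale_to_30(c(0, 21, 70)) # 0, 9, 30
scale_to_30 <- function(total_0_to_70) {
  bad <- !is.na(total_0_to_70) &
    (total_0_to_70 < 0 | total_0_to_70 > 70)
  if (any(bad)) abort("totals must lie in [0, 70]")
  total_0_to_70 * 30 / 70
}

#' Split subjects at the clinical threshold of pain-related facial activity
#'
#' Classifies poststimulus (reactivity) three-action totals on the 0-30
#' scale: totals at or above the threshold (default 9/30) indicate
#' clinically significant pain-related facial activity (`"NFCS-clinical"`),
#' totals below it do not (`"NFCS-subclinical"`). The grouping is defined on
#' poststimulus scores only; baseline scores are rejected.
#'
#' @param scores Tibble with columns `total` and `epoch` (every row must be
#'   a `"reactivity"` epoch), or a bare numeric vector of reactivity totals.
#' @param threshold Clinical cut-off (default 9 on the 0-30 scale).
#' @return The input tibble with a `clinical_group` column (or a character
#'   vector for numeric input); `NA` totals give `NA` groups.
#' @export
#' @examples
#' classify_clinical(c(0, 8.99, 9, 30))
classify_clinical <- function(scores, threshold = 9) {
  if (is.numeric(scores)) {
    return(ifelse(is.na(scores), NA_character_,
                  ifelse(scores >= threshold, "NFCS-clinical",
                         "NFCS-subclinical")))
  }
  if (!"epoch" %in% names(scores) || any(scores$epoch != "reactivity")) {
    abort("clinical grouping is defined on reactivity (poststimulus) scores only")
  }
  dplyr::mutate(scores,
                clinical_group = classify_clinical(.data$total, threshold))
}
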