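#' Write and read epoch sets as delimited text with a JSON sidecar
#'
#' Epochs are stored portably as one tab-separated file per subject
#' (rows = channels, first column the channel name, remaining columns the
#' samples) plus a JSON sidecar carrying the sampling rate, montage, time
#' axis window, reference state and subject ids.
#'
#' @param es An [epoch_set()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default `"epochs"`).
#' @return `write_epochs()`: the sidecar path, invisibly.
#' @export
write_epochs <- function(es, dir, prefix = "epochs") {
  stopifnot(inherits(es, "epoch_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (s in seq_len(dim(es$data)[1])) {
    f <- file.path(dir, sprintf("%s_%s.tsv", prefix, es$subject_ids[s]))
    m <- es$data[s, , ]
    utils::write.table(
      data.frame(channel = es$montage, m, check.names = FALSE),
      f, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, basename(f))
  }
  sidecar <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(
    list(fs_hz = es$fs_hz, montage = es$montage,
         window_ms = c(es$times_ms[1],
                       es$times_ms[length(es$times_ms)] + 1000 / es$fs_hz),
         reference = es$reference, subject_ids = es$subject_ids,
         files = files),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' @param sidecar Path to the JSON sidecar written by [write_epochs()].
#' @rdname write_epochs
#' @return `read_epochs()`: the reconstructed [epoch_set()].
#' @export
read_epochs <- function(sidecar) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dir <- dirname(sidecar)
  subs <- lapply(meta$files, function(f) {
    d <- utils::read.table(file.path(dir, f), sep = "\t", header = TRUE,
                           check.names = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    dimnames(m) <- NULL
    m
  })
  times <- epoch_times(meta$window_ms, meta$fs_hz)
  epoch_set(subs, meta$fs_hz, times, meta$montage, meta$reference,
            subject_ids = meta$subject_ids)
}

#' Write and read facial coding tables as delimited text
#'
#' One row per subject x epoch x action with columns `t1..t10`; missing
#' cells are stored as `NA:<reason>` so the obstruction reason survives the
#' round trip. Constancy flags travel with every row.
#'
#' @param coding Long coding tibble (see [generate_facial_cohort()]).
#' @param path Output file path (tab-separated).
#' @return `write_facial_coding()`: `path`, invisibly.
#' @export
write_facial_coding <- function(coding, path) {
  cell <- ifelse(is.na(coding$value),
                 paste0("NA:", ifelse(is.na(coding$missing_reason),
                                      "unspecified", coding$missing_reason)),
                 as.character(coding$value))
  wide <- coding |>
    dplyr::mutate(cell = cell, second = paste0("t", .data$second)) |>
    dplyr::select(dplyr::any_of(c("subject_id", "group", "epoch", "action",
                                  "cry_constant", "body_constant",
                                  "coder_override")),
                  "second", "cell") |>
    tidyr::pivot_wider(names_from = "second", values_from = "cell")
  utils::write.table(wide, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_facial_coding
#' @return `read_facial_coding()`: the long coding tibble.
#' @export
read_facial_coding <- function(path) {
  wide <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE,
                            colClasses = "character")
  long <- tidyr::pivot_longer(wide, dplyr::matches("^t[0-9]+$"),
                              names_to = "second", values_to = "cell")
  long |>
    dplyr::mutate(
      second = as.integer(sub("^t", "", .data$second)),
      value = suppressWarnings(as.integer(.data$cell)),
      missing_reason = ifelse(startsWith(.data$cell, "NA:"),
                              sub("^NA:", "", .data$cell), NA_character_),
      dplyr::across(dplyr::any_of(c("cry_constant", "body_constant",
                                    "coder_override")), as.logical)
    ) |>
    dplyr::select(-"cell") |>
    dplyr::arrange(.data$subject_id, .data$epoch, .data$second) |>
    tibble::as_tibble()
}

#' Write a synthetic-cohort manifest
#'
#' Records, per subject, the group, the generating seed, and the
#' ground-truth script realized for that subject, as JSON.
#'
#' @param cohort Result of [generate_erp_cohort()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cohort_manifest <- function(cohort, path) {
  spec <- cohort$spec
  jsonlite::write_json(
    list(seed = spec$seed, fs_hz = spec$fs_hz,
         epoch_window_ms = spec$epoch_window_ms,
         n_subjects_per_group = spec$n_subjects_per_group,
         montage = spec$montage,
         subjects = lapply(split(cohort$ground_truth,
                                 cohort$ground_truth$subject_id),
                           function(d) {
                             list(subject_id = d$subject_id[1],
                                  group = d$group[1],
                                  events = d[, c("template_id", "onset_ms",
                                                 "duration_ms",
                                                 "amplitude_uv")])
                           })),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
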