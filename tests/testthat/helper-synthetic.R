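# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

fixed_templates <- function(k, n_channels = 18, seed = 42) {
  painstates:::with_seed(seed, make_templates(k, n_channels))
}

# a small two-template cohort with disjoint scripted intervals
small_script <- function(templates, snr = 10, jitter_sd_ms = 5,
                         onsets = c(100, 500), durations = c(200, 200),
                         amplitude = 4) {
  ids <- rownames(templates)[seq_along(onsets)]
  microstate_script(
    tibble::tibble(template_id = ids, onset_ms = onsets,
                   duration_ms = durations,
                   amplitude_uv = amplitude),
    templates, jitter_sd_ms = jitter_sd_ms, snr = snr)
}

small_cohort <- function(n = 6, snr = 10, fs = 250, seed = 7,
                         templates = fixed_templates(2),
                         script_b = NULL, ...) {
  sa <- small_script(templates, snr = snr, ...)
  sb <- if (is.null(script_b)) sa else script_b
  generate_erp_cohort(cohort_spec(n, list(sa, sb), fs_hz = fs, seed = seed))
}

# complete (no missingness) coding tibble for one subject/epoch from a
# 7 x 10 matrix
coding_from_matrix <- function(m, subject_id = "S01", epoch = "reactivity",
                               cry = TRUE, body = TRUE, override = FALSE) {
  tibble::tibble(
    subject_id = subject_id, epoch = epoch,
    action = rep(nfcs_actions(), times = 10),
    second = rep(1:10, each = 7),
    value = as.vector(m),
    missing_reason = ifelse(is.na(as.vector(m)), "obstructed", NA_character_),
    cry_constant = cry, body_constant = body, coder_override = override
  )
}
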