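Package: painstates
Title: Neonatal Pain-Related Facial Coding and EEG Microstate Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links clinical thresholds in neonatal pain-related facial
    activity to event-related EEG microstate dynamics. Implements Neonatal
    Facial Coding System (NFCS) constellation scoring with structured
    missing-data rules (facial symmetry, cry/body-movement constancy fill,
    proration, exclusion) and a 9/30 clinical threshold; reference-independent
    topographic statistics (global field power, the dissimilarity index,
    topographic ANOVA and the topographic consistency test with
    randomization nulls and run-length control); microstate identification by
    atomize-and-agglomerate hierarchical clustering with split-half
    cross-validation, template back-fitting, baseline-topography activation
    nulls and event extraction (onset, duration, power); and group
    comparison of microstate parameters against phase-randomized surrogate
    nulls. A seeded synthetic-data module generates ground-truthed
    stimulus-locked EEG cohorts and second-by-second facial coding matrices
    so the full pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
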