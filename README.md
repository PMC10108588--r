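# painstates

Neonatal pain-related facial coding and EEG microstate analysis.

After a clinically required heel lance, newborns show both pain-related
facial activity — scored second-by-second with the Neonatal Facial Coding
System (NFCS) — and a stimulus-locked cortical response measurable with
EEG. Clinical practice thresholds the behavioural score to decide whether
pain is "clinically significant"; the scientific question is whether that
threshold corresponds to a difference in *how* the brain processes the
stimulus, not merely in how strongly. `painstates` implements the full
analysis chain for that question, for researchers working with evoked
responses and behavioural coding in neonates:

* **NFCS scoring** of 7-action × 10-second coding tables for the NFCS-7,
  NFCS-3 and PIPP-R-aligned NFCS-P-3 constellations, with the structured
  missing-data rules used for obstructed video (facial symmetry, the
  cry/body-movement constancy fill, proration, exclusion) and the 9/30
  clinical threshold; Friedman/Wilcoxon/Mann–Whitney constellation
  comparisons and ICC(2,1) plumbing.
* **Topographic statistics** that are reference-independent: global field
  power (GFP, the population SD across electrodes), the dissimilarity
  index (DISS, with DISS² = 2(1−r)), the TANOVA subject-permutation test
  of map differences, and the topographic consistency test (TCT,
  channel-shuffle null), each with exceedance p-values and a 5%-of-window
  run-length rule against multiple comparisons over time.
* **Microstates**: atomize-and-agglomerate hierarchical clustering of
  pooled consistent topographies, split-half cross-validated choice of the
  number of states, back-fitting by squared spatial correlation,
  activation testing against baseline-topography nulls, and event
  extraction (onset ms, duration ms, power µV·ms).
* **Group comparison** of microstate parameters and total field power
  against randomization nulls built by regrouping (label permutation by
  default; a phase-randomized surrogate variant behind the same
  interface), at the conventional p < 0.025-per-tail threshold; pooled-t
  and 2×2 chi-square demographics.
* **Synthetic cohorts** with known ground truth — scripted microstate
  sequences in spatially correlated 1/f noise at controlled SNR, and
  facial coding tables with obstruction-driven missingness — so the whole
  pipeline is testable end to end without clinical recordings.

EEG preprocessing (zero-phase Butterworth band-pass/notch, common-average
re-referencing, stimulus-locked epoching, spherical-spline channel
interpolation on idealized 10/20 positions) is included for delimited
numeric input; artifact ICA is out of scope.

## Worked example

```r
library(painstates)

# a two-state script: which topographies engage, when, how strongly
tm <- with(list(), {set.seed(42); make_templates(2, 18)})
script <- microstate_script(
  tibble::tibble(template_id = c("M1", "M2"),
                 onset_ms    = c(100, 500),
                 duration_ms = c(200, 200),
                 amplitude_uv = 4),
  tm, jitter_sd_ms = 5, snr = 10)

coh <- generate_erp_cohort(cohort_spec(12, list(script, script),
                                       fs_hz = 250, seed = 7))
coh$epochs$group1
#> <epoch_set> 12 subjects x 18 channels x 375 samples @ 250 Hz, common average reference
#>   window [-500, 1000) ms

# where is the topography consistent across subjects?
r <- tct(coh$epochs$group1, window_ms = c(-200, 1000),
         n_iter = 1000, seed = 1)
r
#> <randomization_result: tct> 300 timepoints, 1000 iterations
#>   alpha 0.05, minimum run 60 ms; 2 significant segment(s)
#>     [100, 300) ms
#>     [500, 708) ms
```

The two consistent segments recover the scripted engagements (100–300 and
500–700 ms; the 8 ms overhang on the second is the across-subject onset
jitter). `pool_consistent_maps()` + `select_k()` + `cluster_microstates()`
then identify the templates, `fit_microstates()` +
`activation_significance()` + `extract_events()` turn them into events,
and `surrogate_compare()` tests group differences in their parameters.
`run_pipeline(validate_config(list(seed = 1)), "out/")` executes the whole
chain per cohort and writes CSV/JSON outputs with a reproducible run
record; every numeric default (1–30 Hz band, 48–52 Hz notch, −500…1000 ms
epochs, 5000 randomization iterations, 100 CV iterations, 5% run-length
rule, 9/30 threshold, α = 0.05 / 0.025 two-tailed) lives in
`default_config()`.

The distribution of synthetic NFCS-P-3 totals, the clinical split, and the
constellation comparison:

```r
fc <- generate_facial_cohort(facial_sim_spec(50, c(0.8, 0.1), seed = 6))
scores <- score_nfcs(fc$coding, "nfcs_p3")
react  <- classify_clinical(dplyr::filter(scores, epoch == "reactivity"))
table(react$group, react$clinical_group)
#>
#>            NFCS-clinical NFCS-subclinical
#>     group1            49                0
#>     group2             0               49
```

(One subject per group fell below the 60% coding-coverage floor after
obstruction and was excluded rather than prorated.)

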