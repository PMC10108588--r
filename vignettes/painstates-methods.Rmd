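---
title: "Methods: topographic statistics, microstates, and NFCS scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topographic statistics, microstates, and NFCS scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painstates)
```

## What this package models

`painstates` links a behavioural measure of neonatal pain — second-by-second
Neonatal Facial Coding System (NFCS) scores after a heel lance — to the
dynamics of the stimulus-locked EEG response, analysed not as a waveform at
one electrode but as a sequence of quasi-stable scalp topographies
(*microstates*). The pipeline is: score facial actions and split subjects at
a clinical threshold; test where the evoked topography is reliable (TCT) and
where it differs between groups (TANOVA); identify microstate templates by
clustering the reliable topographies; back-fit them to group averages; and
compare event parameters (onset, duration, power) between the
clinical-threshold groups against randomization nulls.

All of it runs on synthetic cohorts with known ground truth, because the
clinical recordings behind the original analyses are not publicly
deposited. The synthetic-data module is therefore first-class, tested code:
it defines the study conditions under which every downstream claim is
verified.

## Topographic statistics

For an average-referenced map $v$ over $C$ electrodes, the global field
power is the population standard deviation
$\mathrm{GFP}(v) = \sqrt{\tfrac1C\sum_i (v_i - \bar v)^2}$ (µV). It is
invariant to the recording reference. The dissimilarity index between maps
$u, v$ with nonzero GFP is

$$\mathrm{DISS}(u,v) \;=\; \sqrt{\tfrac1C \sum_i \left(
  \frac{u_i}{\mathrm{GFP}(u)} - \frac{v_i}{\mathrm{GFP}(v)}
\right)^2} \in [0, 2],$$

with 0 for identical configurations and 2 for polarity reversal, and the
identity $\mathrm{DISS}^2 = 2(1-r)$ with $r$ the spatial Pearson
correlation — used as an internal cross-check at tolerance 1e-9.

**TANOVA** compares the two group-average maps by DISS at every timepoint;
the null permutes subjects across groups (sizes preserved). **TCT** asks
whether subjects share a topography: the statistic is the GFP of the
grand average, and the null shuffles each subject's channels independently.
Both use right-tailed exceedance p-values with the +1 correction,
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_\text{iter})$, so the
identity permutation is in the null set and p-values are valid by
construction. Multiple comparisons over time are controlled by a
*run-length rule*: only runs of consecutively significant samples covering
at least 5% of the tested window survive (75 ms for a 1500 ms epoch, 60 ms
for the 1200 ms consistency window, 50 ms for the 1 s post-stimulus
period). The TCT window opens 200 ms before the trigger because the exact
release of the lance carries timing uncertainty.

## Microstates

Grand-average maps at TCT-consistent timepoints from all groups are pooled,
GFP-normalized (their GFP retained as weights), and clustered by an
atomize-and-agglomerate hierarchical scheme (AAHC): starting from
singletons, the cluster contributing least explained variance
$\sum_{i \in c} (w_i\, r(v_i, t_c))^2$ is dissolved and its members
reassigned to the most-correlated remaining template; templates are
weighted means renormalized to unit GFP. Clustering and fitting are
polarity-sensitive by default (the evoked-response convention); a toggle
inverts this. The published description of this clustering family leaves
implementation details open; the variant here is documented, not asserted
identical to any toolbox.

The number of states $k^*$ comes from split-half cross-validation: subjects
are split 50/50 within each group (100 iterations), templates fitted on the
training half, and held-out explained variance
$\sum_t (\mathrm{GFP}_t \max_m r_{tm})^2 / \sum_t \mathrm{GFP}_t^2$
evaluated on the test half. $k^*$ is the last $k$ before the mean gain of
one more template drops below one percentage point. Two remarks. First, the
rule is a marginal-gain elbow; the phrasing "smallest k whose gain is below
threshold" would return $k_\text{true}+1$ and contradicts planted-truth
recovery, so the elbow reading is used. Second, the rule has a known
limitation on structureless data: random templates in an 18-channel
average-referenced map space still gain roughly 2–5 percentage points of
held-out explained variance per extra template at small $k$, so on pure
noise the curve creeps upward without an elbow and $k^*$ runs to the top of
the range. The honest null signature is the absence of an elbow and a low
plateau, and that is what the tests assert.

Back-fitting projects every timepoint's average map onto each template:
$c_m(t) = \max(r, 0)^2$ (squared spatial correlation; negative correlations
explain nothing under the polarity-sensitive convention). A template is
*active* where $c_m(t)$ exceeds the variance explained by random baseline
topographies — maps drawn with replacement from every subject's
prestimulus period — in runs of at least 50 ms. The threshold is the
$k$-th largest of the $n$ null draws with $k = \lfloor \alpha(n+1)
\rfloor$ (the +1-corrected randomization threshold, exceeded with
probability exactly $k/(n+1) \le \alpha$ under exchangeability; an
interpolated percentile would be anti-conservative at finite $n$).
Contiguous active runs become events; two runs of one template merge when
their gap does not exceed that template's mean run duration pooled across
occurrences and groups. Events carry onset (ms, negative onsets possible
since the fitted window starts before the stimulus), duration (ms), and
power $\sum_t \mathrm{GFP}(t)\, c_m(t)\, \Delta t$ (µV·ms; the
microvolt-millisecond reading of the power unit is used throughout).

## Group comparison

Observed differences in event onset, duration, power, and in total field
power (mean GFP over the post-stimulus second) are tested against a null
built by "generating two random groups", refitting, and re-extracting the
parameters, with null events anchored to the observed events' latencies.
The default generator is **label permutation** of the original subjects:
under the null of identical group processes subjects are exchangeable, so
the difference null is exactly calibrated, preserves the common event
structure, and is tight enough to resolve tens-of-milliseconds onset
shifts. A **phase-surrogate** variant is provided (each subject replaced by
the pooled average plus a common-phase Fourier randomization of its
residual, then regrouped): it preserves per-channel amplitude spectra and
the instantaneous topographic structure exactly while destroying
stimulus-locked deviations. It was not made the default because common-phase
randomization leaves surrogate averages template-correlated at arbitrary
latencies; the resulting null conditions on events at random positions and
its onset-difference band is an order of magnitude wider (~±150 ms against
~±8 ms in simulation), which makes it a test of event existence rather
than of parameter differences. Two-tailed p-values use the +1 correction;
the conventional threshold is p < 0.05 two-tailed, i.e. 0.025 per tail.
Events present in only one group are reported as incomparable rather than
differenced. One calibration caveat: power parameters are continuous and
their rejection rate sits at the nominal size, but onsets and durations
are multiples of the sampling step, so their permutation nulls carry
large atoms and the exact test is conservative for them (size bounded by
$\alpha$, approached only as temporal resolution grows) — the usual
property of randomization tests on discrete statistics.

Demographic plumbing uses the pooled-variance two-sample t statistic from
summary data (Welch available via a flag) and the uncorrected Pearson
chi-square for 2×2 tables; both are cross-checked against `stats::t.test`
and `stats::chisq.test` in the tests.

## NFCS scoring and missing data

Seven facial actions are coded 0/1 per second over a 10 s baseline and a
10 s reactivity epoch (maxima 70 for the seven-action constellation, 30 for
the three-action ones; the seven-action total rescales to 0–30 by
$\times 30/70$). Missing codes from face obstruction are handled in a fixed
order: facial symmetry (a coder-side judgement, passed through), the
constancy rule (per action: with ≥60% of the action's seconds codable,
cry and body movements constant, and no coder objection, missing cells take
the closest preceding observed value, or the closest following value —
flagged — when the gap opens the epoch), proration (with ≥60% of the
constellation's cells observed, the total is the observed sum scaled by
total/observed cells, capped at the maximum), and otherwise exclusion.
Proration is gated only on the 60% overall-coverage condition; the
constancy of the auxiliary distress behaviours is required only for the
fill rule. Totals at or above 9 on the 0–30 reactivity scale define the
clinically significant group; the split is deterministic and monotone in
the total.

The constellation comparison is nonparametric throughout: Friedman test
across paired constellations (completely tied data are reported as
$\chi^2 = 0$, $p = 1$), Wilcoxon signed-rank Z from the tie-corrected
normal approximation with continuity correction (exact sign-flip
enumeration with the observed average ranks below n = 10), and
Mann–Whitney U between cohorts. The two-way random-effects,
absolute-agreement, single-rater intraclass correlation is provided for
interrater reliability; with no between-subject variance it is undefined
and returns 0 with a warning.

## The synthetic cohorts

EEG: each group follows a *microstate script* — average-referenced,
unit-GFP templates engaged as boxcars with 10 ms half-cosine edges at
scripted onsets, durations and amplitudes. Across-subject onset jitter is
Gaussian (SD 10 ms by default, truncated so events stay inside the epoch),
mirroring the uncertainty in the stimulus release. Noise is per-channel
$1/f^\alpha$ ($\alpha = 1$) mixed by a Gaussian spatial kernel over
great-circle electrode distance (width 0.6 rad) and scaled per subject so
the epoch-wise signal-to-noise power ratio equals the requested `snr`;
with no scripted signal the noise has unit RMS. Everything is
common-average referenced, and identical spec + seed gives bit-identical
cohorts. The defaults — 18 channels on idealized 10/20 spherical positions,
500 Hz (2 kHz supported), epochs −500…1000 ms, SNR 5, 20 subjects per
group — are the conditions under which the recovery properties are stated.
Facial coding: per-second Bernoulli action probabilities of 0.8 vs 0.1 for
the two groups (baseline 0.02) reproduce the strongly bimodal total-score
distribution with most subjects at the scale extremes; obstruction arrives
in Poisson bouts (rate 0.3 per epoch, mean length 2 s) hiding all seven
actions, with cry/body constancy flags drawn at probability 0.8.

What the generator does **not** emulate: volume conduction and realistic
neonatal head geometry, non-stationary or artifactual noise (ECG,
movement), coder disagreement, and any dependence between facial and
cortical responses beyond shared group membership. Passing tests therefore
demonstrate that the statistical machinery is correct and well calibrated
under these assumptions — not that the scientific conclusions transfer to
any particular clinical recording.

## Numerical choices and problem sizes

Filters are second-order Butterworth, applied forward–backward
(zero-phase, effective fourth-order magnitude): band-pass 1–30 Hz, then
band-stop 48–52 Hz. Epochs are half-open windows with t = 0 on the trigger
sample and `round((end-start)·fs/1000)` samples. Bad channels (at most 4)
are reconstructed by spherical splines (stiffness order m = 4, 7 Legendre
terms) on idealized unit-sphere 10/20 coordinates constructed geometrically
(arcs at 45°/18° steps, great-circle midpoints for intermediate sites);
the spline reproduces constants exactly. Zero-GFP timepoints get p = 1 in
TANOVA and are masked in back-fitting. Ties in clustering dissolve the
first-indexed worst cluster, making results deterministic under a seed.
EDF I/O is not provided; epochs serialize as per-subject delimited text
with a JSON sidecar, facial tables as delimited text with `NA:<reason>`
cells.

The test suite scales iteration counts to desk size as its own design
choice: type-I calibration uses 200 randomization iterations × 50
simulated cohorts per test; the pipeline-level recovery cohort uses 20
subjects per group at 500 Hz with 1000-iteration TCT nulls, the full
100-iteration cross-validation, 2000-draw activation nulls and a
1000-iteration comparison null. The analysis defaults remain 5000
iterations for every randomization null and are what `run_pipeline()`
uses unless overridden.

## Known limitations

* The k\* elbow rule needs a genuinely low-dimensional signal to produce an
  elbow; on structureless data it saturates at the top of the candidate
  range (see above).
* The surrogate-null reconstruction is one defensible reading of a
  published-but-unrestated recipe; its validity here rests on its own
  type-I calibration, and the phase-surrogate alternative is kept behind
  the same interface for sensitivity analysis.
* Activation nulls compare baseline topographies against the group-average
  map; a per-subject variant is not implemented.
* ICA-based artifact removal is out of scope; `denoise_hook()` marks where
  a user-supplied denoiser belongs.
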