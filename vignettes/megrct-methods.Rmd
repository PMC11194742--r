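---
title: "Analyzing intervention-driven change in category-selective visual cortex with megrct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing intervention-driven change in category-selective visual cortex with megrct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megrct)
```

## The analysis problem

A pre/post randomized controlled trial measures evoked MEG responses to
three visual categories (Words, Faces, Cars) in two intervention arms
(a Letter/literacy arm and a Language control arm). The scientific
question is whether the intervention changes category selectivity in a
region of ventral occipitotemporal cortex — and, if so, whether a gain
in the Words response is coupled to a loss in the response to other
categories (the competition signature predicted by neuronal recycling).

`megrct` implements the full statistical pipeline for such a trial:

1. **Epoch rejection tuned for reliability** — peak-to-peak amplitude
   thresholds per sensor type, chosen by a grid search that maximizes
   the test–retest reliability of the evoked response across sessions.
2. **ROI time-course extraction** — SVD-based aggregation of a
   multi-channel (or multi-vertex) region into one time course, with
   orientation sign flipping and power-matched scaling.
3. **Data-driven analysis window** — the first prominent peak of the
   pre-intervention grand average, ± 50 ms.
4. **Mixed-effects contrasts** — the three-way group × condition × time
   interaction and its Words-vs-Cars / Words-vs-Faces components, with
   Satterthwaite denominator degrees of freedom.
5. **Temporal cluster permutation** — a from-scratch max-mass cluster
   test on per-subject change time courses, comparing arms.
6. **Competition correlations** — Pearson correlations between the
   per-subject change in the Words response and each other category.

Everything is exercised end to end on a synthetic-data generator with
known ground truth, so every stage is testable without recordings.

## The synthetic study generator

`simulateEpochs()` produces one `EpochsSet` (trials × channels × time)
per subject × session. Each trial is a cell-specific evoked amplitude
times a Gaussian temporal kernel, loaded onto channels by their sensor
type's amplitude scale, plus white per-sample noise; a configurable
fraction of trials carries a large square artifact transient on a
random subset of one sensor type's channels.

Design defaults follow the reference trial: 24 subjects per arm, 30
trials per condition per session, 1.1 s epochs with a 100 ms
pre-stimulus baseline, and a single evoked peak at 175 ms (SD 40 ms).
Two sensor types with a 20× amplitude-scale disparity stand in for
gradiometers and magnetometers. The default sampling rate is 200 Hz —
enough to resolve a 40 ms-wide evoked component, and chosen so the
175 ms peak falls exactly on the sampling grid (which makes the
noise-free generator exactly invertible, a property the test suite
relies on).

The evoked amplitude of subject *i*, session *s*, condition *c*
decomposes as

\[ a_{isc} = \mu_{g(i),c,s} + b_i + g_{is} + o_{ic} + e_{isc} , \]

with a subject intercept \(b_i\) (SD 0.4), a subject × session gain
\(g_{is}\) (SD 0.4) shared across conditions, a subject × condition
offset \(o_{ic}\) (SD 0.2) stable across sessions, and a residual cell
jitter \(e_{isc}\) (SD 0.1); per-sample trial noise has SD 1 in
unit-scale channels. The session gain is deliberately the dominant
within-subject term: in real MEG, session-to-session differences in
head position and vigilance move all conditions together. Two
consequences the package's analyses exploit (and which match what such
trials report):

* condition *contrasts* are far more precise than raw responses,
  because the shared gain cancels; and
* post-minus-pre changes are positively correlated across conditions,
  so the competition correlation is positive under the null of "no
  competition" — exactly the shared-gain interpretation offered for
  positive change correlations in this literature.

`withinSubjectSd()` returns the total within-subject cross-session SD,
\(\sqrt{0.4^2 + 0.1^2} \approx 0.41\); planted intervention effects are
calibrated against it ("a one within-subject SD enhancement").

What the generator does **not** emulate: colored (1/f) sensor noise,
realistic sensor geometry and field spread, source leakage between
regions, or any forward model. Passing tests therefore demonstrate the
statistical machinery — estimator correctness, calibration, recovery of
planted effects under this noise structure — not robustness to every
property of real recordings.

## Rejection tuning

`peakToPeak()` computes the rejection statistic (max − min per channel
per trial). `applyRejection()` rejects a trial if any channel exceeds
its sensor type's threshold. `tuneThresholds()` evaluates a grid of
threshold pairs: a cell is *untenable* if any subject × session ×
condition loses all its trials; tenable cells are scored by the mean
across subjects of the Pearson correlation between each subject's pre-
and post-session grand-average evoked time course (trials pooled over
conditions) in a designated tuning ROI.

Choices the method leaves open, and how this package resolves them:

* **Tuning-ROI aggregation** is an unweighted (optionally weighted)
  channel mean; the SVD aggregator is reserved for the analysis ROI.
  The default ROI is the first sensor type's channels; passing weights
  of \(1/\text{scale}\) per type pools both sensor types on a common
  scale, which is what lets artifacts on either type hurt the
  objective and hence be rejected.
* **Correlation range**: post-stimulus samples only (t ≥ 0), so the
  objective reflects stimulus-locked signal rather than baseline noise.
* **Tie-break**: among cells attaining the maximum, the most permissive
  wins — largest total retained-trial count, then the first type's
  threshold, then the second's. This generalizes "the higher of the two
  was chosen" to arbitrary ties.
* **Grid construction**: log-spaced candidates from the 50th to the
  100th percentile of the pooled pre-rejection peak-to-peak
  distribution per type. Thresholds below the median reject most
  trials and are almost always untenable; the upper end is "never
  reject".
* **Zero-variance evoked courses** (possible in degenerate synthetic
  data) are excluded from the objective mean with a warning rather
  than propagating `NA`.

Note a structural consequence verified in the tests: enlarging either
threshold never rejects more trials, so retention is componentwise
monotone on the grid, and the grid search is by construction an
exhaustive enumeration (the suite checks it against an independent
naive recomputation).

## ROI aggregation and the analysis window

`svdFlipAggregate()` implements the standard source-space convention:
with SVD \(X = USV^\top\) (vertices × time), the ROI course is

\[ \mathrm{sign}(\langle u_1, \mathrm{flip}\rangle) \cdot
   \frac{\lVert S\rVert_2}{\sqrt{n_v}} \cdot v_1 , \]

i.e. the first right-singular vector scaled to match mean per-vertex
power and sign-flipped toward the dominant dipole orientation. For
identical vertices this returns the input exactly; all-zero input
returns zeros rather than dividing by zero.

`findFirstPeak()` takes the grand average — by default pooled over
**pre-intervention** data only, to avoid letting post-only effects
steer the window — and returns the earliest local maximum in
50–500 ms whose prominence exceeds 10% of the waveform's range in the
search window. Under noise, "first peak" is ill-defined without a
prominence floor; 10% suppresses noise ripples while keeping any
plausible evoked component. `defineWindow()` then takes ± 50 ms around
the peak (a 175 ms peak gives 125–225 ms; a 185 ms peak gives
135–235 ms — both windows reported for this procedure in the
literature), and `windowMean()` averages over the closed interval,
snapping to the sampling grid with a tolerance far below one sample.

## Mixed-effects contrasts

`fitThreeWay()` fits `response ~ group * condition * time` with dummy
coding (references: Language arm, Words, pre) and per-subject random
intercepts and slopes for all within-subject effects, estimated by
REML. With one window-averaged response per subject × condition × time
the maximal structure is saturated (six observations against six
random effects per subject), so a recorded fallback ladder simplifies
only the random structure — correlated slopes → additive slopes →
time-only → intercept-only → fixed-effects-only least squares — never
the fixed-effect coding. Wald t and F tests use Satterthwaite
denominator degrees of freedom (hence fractional df), via lmerTest.
The Words-vs-Cars and Words-vs-Faces three-way t statistics are the
`group:conditionCars:timepost` and `group:conditionFaces:timepost`
coefficients — with Words as reference, they measure how the Words
change differs from each comparison category's change across arms.

The companions: `fitGroupByTime()` (behavioral scores or a single
condition; random intercept + time slope; also per-arm time-only
models), and `fitConditionByGroup()` (one time point; random intercept
only, since each subject contributes one response per condition).
`cohensD()` uses the equal-n pooled-SD convention
\(\sqrt{(s_1^2+s_2^2)/2}\), which reproduces the published 4.65 from
the cited group summaries, and `tTestPower()` evaluates the exact
noncentral-t power with noncentrality \(d\sqrt{n/2}\) and \(2n-2\) df.

Calibration, verified by simulation in the acceptance suite: the null
rejection rate of the three-way interaction at α = 0.05 lies in
[0.03, 0.08] over 500 replicates of the default generator, and in the
zero-noise limit every fit reproduces its generating coefficients to
10⁻⁶. No multiple-testing correction is applied beyond the a priori
window and the cluster procedure — mirroring the analysis this package
operationalizes.

## Temporal cluster permutation

`permutationTest()` compares per-subject change time courses (e.g.
\((\text{Words}-\text{Cars})_{\text{post}} -
(\text{Words}-\text{Cars})_{\text{pre}}\)) between arms over
0–500 ms: pointwise pooled-variance t, maximal runs with
\(|t| >\) threshold, cluster mass = sum of t over the run, and a null
distribution of the maximum absolute cluster mass under subject-level
relabeling (group sizes preserved). Defaults: the cluster-forming
threshold is the two-sided p < 0.05 t quantile at \(n_A+n_B-2\) df,
1024 permutations, two-sided inference by pooling signs in the null.
p-values use the \((1 + \#\{\text{null} \ge |m|\})/(1+B)\) convention
and are never zero; `method = "exhaustive"` enumerates all label
splits for small samples. Zero-variance timepoints get t = 0 and
cannot seed clusters. Ties between a null draw and the observed mass
are counted as exceedances (with a 10⁻⁸ relative tolerance), so a
re-encountered observed split always counts itself.

## Competition correlations

`changeTable()` computes per-subject post-minus-pre window-mean changes
per condition; `changeCorrelation()` reports the Pearson r between the
Words change and another category's change with the exact t-transform
p-value, for the full sample or the Letter arm only — the two subsets
this design reports. A negative r is the competition signature; a
positive r indicates shared gain. The suite verifies that a shared-gain
generator and a zero-sum generator are distinguished with the correct
signs.

## The pipeline, formats, and determinism

`runPipeline(studyConfig(...))` sequences
tune → reject → extract → window → models → clusters → correlations
and returns a result bundle embedding the master seed and an MD5 hash
of the configuration. All JSON is written at 17 significant digits, so
identical configurations produce byte-identical files (the determinism
the acceptance suite asserts). Epochs serialize to a self-describing
JSON layout (`writeEpochs()`/`readEpochs()`, lossless round trip);
study configurations can be read from YAML (`readStudyConfig()`);
tables are CSV. Times are seconds internally, milliseconds only in
reports; stimulus onset is 0 and epochs span −0.1 to 1.0 s.

## Problem sizes used in the shipped checks

The test and acceptance suites run at sizes chosen to exercise the
statistics faithfully while staying quick on one CPU: calibration loops
use 500 replicates of the full 24-per-arm design at the stage level
(change-series and response-table generators); the planted-artifact
tuning check uses 12 subjects × 2 sessions × 90 trials with 5 channels
per type; and the 100 end-to-end planted-truth studies run the full
24-per-arm pipeline at 100 Hz with 3 channels per type and 512
permutations. These sizes are the package's own choices; all stage
defaults remain the reference design values stated above.

## A worked example

```{r example, eval = FALSE}
library(megrct)

wsd <- withinSubjectSd(simulationConfig())
cfg <- studyConfig(
  simulation = simulationConfig(
    amplitudeMatrix = amplitudeDesign(1, lettersWordsPostBoost = wsd)),
  seed = 11)
bundle <- runPipeline(cfg, verbose = TRUE)

bundle$window            # data-driven analysis window
bundle$threeWay          # group x condition x time interaction
bundle$clusters$wordsCars$clusters
bundle$competition$cars_all
```

## Known limitations

* The generator's white-noise and rank-1 channel-loading assumptions
  make the SVD aggregation step easier than on real source estimates;
  the oracle tests cover the algebra, not leakage robustness.
* The cluster test is temporal-only; spatial or spatiotemporal
  adjacency clustering is out of scope.
* The mixed-model fallback ladder treats singular fits as acceptable
  (recorded), which is standard practice but means reported random
  structures can be boundary estimates.
* Real-data ingestion is limited to the package's JSON epochs layout;
  connecting an acquisition-specific reader is the caller's job.
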