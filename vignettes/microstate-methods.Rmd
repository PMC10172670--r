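---
title: "Task-EEG microstate analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-EEG microstate analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(taskstates)
```

This vignette is the package's own account of its science: the segmentation
model and its assumptions, the synthetic cohort the package can generate, the
statistical designs layered on top, and the numerical and design choices made
where the literature leaves the details open.

## 1. The microstate model

Microstate analysis describes multichannel EEG as a sequence of brief periods
(tens to low hundreds of milliseconds) during which the spatial distribution
of scalp voltage — the *topography* — remains quasi-stable while only its
overall strength varies. For stimulus-locked data, the trial-averaged ERP is
segmented, and each state is read as one information-processing stage of the
evoked response.

Three quantities define the machinery. The **global field power**
`GFP(t)` is the population standard deviation (divisor `C`, the channel
count) of the topography at sample `t`; it indexes response strength and
weights all variance accounting. The **spatial correlation** of two
topographies is their Pearson correlation across channels, taken in absolute
value because a topography and its sign-flipped version are generated by the
same configuration of cortical sources — *polarity invariance*. The **global
explained variance**

$$\mathrm{GEV} = \frac{\sum_t \big(\mathrm{GFP}(t)\,
\mathrm{corr}(v_t, a_{L(t)})\big)^2}{\sum_t \mathrm{GFP}(t)^2}$$

is the GFP-weighted fraction of topographic variance a labeling `L` explains
with template maps `a_k`. For average-referenced data and unit-norm zero-mean
maps this reduces to `Σ (a'v)² / Σ ‖v‖²`, which is what the implementation
computes; the test suite verifies the equivalence against a literal
per-sample evaluation of the formula.

### The estimator

`microstates(x, K, ...)` runs the *polarity-invariant modified k-means*:
samples are assigned to the map with maximal squared spatial correlation, and
each map is re-estimated as the dominant eigenvector of the outer-product sum
of its assigned samples — the polarity-invariant analogue of the centroid —
then re-centered and re-normalized. Iteration stops when the relative GEV
change drops below `tol = 1e-6` or after `iterations` (default 1000, a
deliberately generous cap: fits on clean ERPs converge in a handful of
iterations). Because the objective has local optima, the fit is restarted
from `restarts` (default 50) random sample initializations and the best GEV
wins; all randomness flows from the `seed` argument.

Conventions worth stating explicitly:

* data are average-referenced internally (idempotent); the zero channel-mean
  is required for the correlation/normalization algebra above;
* ties in the assignment go to the lowest class index, everywhere, so results
  are deterministic given the seed;
* an emptied class is re-seeded from the worst-explained sample;
* flat (zero-variance) samples get label 0, "unassigned", and contribute only
  to denominators;
* `gfp_peaks = TRUE` restricts clustering to local GFP maxima (a common
  practice); the default clusters every sample of the averaged ERP.

### Choosing the number of classes

`select_n_maps()` fits a range of `K` and reports GEV together with the
predictive residual-variance criterion

$$\mathrm{CV} = \hat\sigma^2 \Big(\frac{C-1}{C-1-K}\Big)^2,\qquad
\hat\sigma^2 = \frac{\sum_t v_t'v_t - (a_{L(t)}'v_t)^2}{T(C-1)},$$

whose penalty diverges as `K` approaches `C − 1` (the call errors there with
a message naming the offending term). The returned optimum is the CV
minimizer, but the full table is kept so users can apply the joint "larger
GEV, smaller CV" judgment. In the package's validation experiments, selection
is run on several seconds of data (a few thousand samples): on one short
epoch, classes with few visits make the criterion noisy, exactly as in
practice where selection is done on stacked or grand data.

### Backfitting and the four parameters

`predict(fit, newdata)` (or `backfit()`) labels each sample of a new ERP with
the best-correlated template. `compute_parameters()` then reports, per class:

* **GEV share** — the class's term in the GEV partition (shares sum to the
  total exactly);
* **duration** (ms) — mean length of the maximal runs of the class,
  edge-touching runs included;
* **coverage** — fraction of assigned samples carrying the class;
* **occurrence** (1/s) — number of runs divided by the epoch length.

With the full epoch as the occurrence denominator,
`occurrence × duration/1000 = coverage` holds as an exact identity whenever
every sample is assigned; the test suite asserts it to 1e-9. Published
toolboxes disagree on the denominator, so an `"assigned"` convention
(divide by assigned time instead) is available; the default is the epoch
convention because it preserves the identity. Classes never observed in a
labeling get coverage and occurrence 0 and an `NA` duration — a duration of
an unobserved state is undefined, and the statistics stage treats those cells
as missing (listwise removal per ANOVA, with a logged count).

An optional temporal smoothing (`smooth_labels()`) re-assigns segments
shorter than a minimum duration to the better-correlated neighbor. It is off
by default: the segmentation is reported as fitted unless the user opts in.

## 2. The synthetic cohort generator

No public recordings accompany the motivating study, so the generator is a
first-class module producing data with known ground truth at the study's
geometry: 64-channel extended 10-20 montage, epochs of −200…1000 ms at
500 Hz, three groups of 20/52/66 subjects (healthy controls, depressed
adolescents, depressed adolescents with nonsuicidal self-injury), 150 neutral
and 50 negative-cue trials, and optionally two treatment arms × two times.

* **Maps**: each prototype is the scalp field of a random point dipole inside
  the sensor sphere (location at 0.6 of the radius, random moment), centered
  and normalized; candidates correlating above 0.7 (absolute) with an
  accepted map are redrawn. Dipolar fields are smooth and realistically
  correlated across neighboring sensors without simulating volume conduction.
* **Segments**: per-class mean durations are planted per group × cue (× time)
  cell, at the magnitudes and directionality of the motivating study's
  parameter tables — class 3 dwell time elevated in the patient groups and
  further under negative cues, class 6 shortened in the self-injury group,
  class 4 brief throughout; the longitudinal targets normalize classes 3/6 in
  both arms after treatment and additionally shift classes 1/2/4 in the
  combined medication + rTMS arm. Segment lengths are gamma with shape 4
  (unimodal, realistic dwell-time spread; the shape is a modeling choice, no
  generative model is published).
* **Sequences**: each subject × cell gets one label sequence built by cycling
  a subject-specific random permutation of the classes, with the gamma
  lengths rescaled to fill the epoch exactly. Balanced visits make planted
  coverage track the duration targets with neither visit-count noise nor
  truncation bias — the generator's coverage contract (cell means within
  ±0.03 of targets) is tested at full study scale. Between-subject
  variability is a log-normal multiplier (sd 0.25 on the log scale) on the
  subject's duration targets, drawn once per subject and reused across times
  so repeated measures are genuinely paired; the recorded ground-truth
  targets are these subject-level values.
* **Trials**: all trials of a cell share the signal (labels and a half-sine
  GFP envelope per segment) and differ in spatially/temporally white noise
  scaled so that mean signal GFP over mean noise GFP equals the requested
  `snr` (default 5). Trial averaging therefore behaves as in real ERP work:
  noise shrinks with the trial count, the topography sequence does not. A
  per-trial latency jitter parameter exists (default 0 ms; no published value
  to emulate).
* **Scales**: clinical scores are truncated normal draws at the published
  group/arm/time means and SDs (HAMD 0–52, PHQ-9 0–27, self-injury score
  ≥ 0, age 12–17), with a shared latent subject quantile inducing pre/post
  and cross-scale correlation (ρ = 0.5). Sex is Bernoulli at the group's male
  proportion. Note the truncation: for cells whose mean sits near a bound
  (healthy controls' depression scores) the realized mean is the truncated
  normal's mean, not the nominal one; tests compare against the analytic
  truncated mean.

What the generator does **not** emulate: volume-conducted sensor covariance
from a head model, ocular/muscle artifacts (amplitude-threshold rejection
stands in for the full artifact pipeline; independent-component cleaning is
out of scope and flagged as an external step for real data), latency/topography
nonstationarity across trials, and behavioral responses (the
correct-response filter is a pass-through hook). Passing tests therefore
demonstrate correctness of the machinery and recoverability under controlled
conditions, not performance on real recordings.

## 3. Preprocessing

The trial pipeline is: resample → artifact rejection (peak-to-peak over
channels, default limit 100 µV — "large artifact" is unquantified in the
field, and 100 µV is the common screening value) → trial averaging →
band-pass 0.1–30 Hz → epoch/baseline (half-open `[−200, 1000)` ms grid, so
1200 ms at 500 Hz is exactly 600 samples; baseline window `[−200, 0)` ms) →
average reference.

Numerical choices:

* **Resampling** is FFT-domain (spectrum truncation/zero-padding), exact for
  band-limited content and ideally anti-aliased when downsampling; the test
  oracle is an analytic sine. Content at the retained Nyquist bin is not
  disambiguated — irrelevant after a 30 Hz low-pass at 500 Hz.
* **Filtering** is a cascade of zero-phase (forward–backward) Butterworth
  filters: order-2 high-pass at 0.1 Hz and order-4 low-pass at 30 Hz. A
  single band-pass design spanning 0.1–30 Hz at 500 Hz is numerically
  fragile (the low edge sits at 4e-4 of Nyquist); the cascade meets the
  stated contracts — mid-band loss < 5%, attenuation ≥ 90% at twice the high
  edge — with stable polynomials.
* **Ordering**: filtering, epoching, baseline and referencing are linear, so
  the pipeline applies them after trial averaging. The result is identical
  by linearity (the commutation of averaging and referencing is itself a
  tested property) at a small fraction of the cost; rejection, the only
  nonlinear step, still sees raw trials.

Bad channels are rebuilt as the inverse-distance-weighted mean of the 6
nearest good sensors on the unit sphere — deliberately simpler than
spherical-spline interpolation (a non-goal), and tested to beat
nearest-neighbor substitution on smooth fields.

## 4. The statistical designs

`mixed_anova()` reproduces the SPSS-style univariate repeated-measures table:
Type III sums of squares from a multivariate linear model on the within-cell
responses (delegated to `car::Anova`), up to two within-subject factors, one
between-subject factor, and between-subject covariates. Choices the
motivating analyses leave open, and how this package resolves them:

* **Sum-of-squares type**: Type III, each effect adjusted for all others —
  the mainstream convention of the statistics package the field uses.
* **Covariates**: age and sex (0/1-coded) are mean-centered and enter the
  between-subject model; the between-subject error degrees of freedom are
  `N − groups − covariates` (e.g. 138 − 3 − 2 = 133 at full scale, 32 at the
  scaled-down default), and the same denominator carries to the within
  strata under the multivariate approach. Covariate × within rows are
  reported so the absorption is visible.
* **Sphericity**: Greenhouse–Geisser epsilon is computed from the
  orthonormal-contrast-transformed covariance; it is exactly 1 for two-level
  factors (all the designs here), and both corrected and uncorrected
  degrees of freedom are reported, so the correction is visible rather than
  silent. The standalone estimator `greenhouse_geisser_epsilon()` is tested
  against compound-symmetric and arbitrary PSD matrices.
* **Effect size**: partial eta squared, `SS_effect / (SS_effect + SS_error)`
  within the effect's stratum.
* **Simple effects** (`simple_effects()`): the other factor of a significant
  two-way interaction is tested within each level of the slicing factor. By
  default the error term comes from the omnibus strata — pooled
  between + interaction error when the tested factor is between-subject, the
  interaction stratum when it is within — with a per-slice option
  (`error = "slice"`); pairwise follow-ups are Holm-adjusted within slice.
* **Degenerate inputs**: a constant response yields F = 0, p = 1 by
  convention rather than 0/0; a covariate collinear with the grouping factor
  triggers a warning; subjects missing a within cell are removed listwise
  with a logged count.

`oneway_anova_from_summary()` rebuilds between/within sums of squares from
published means, SDs and group sizes. Because such inputs are rounded to 2–3
decimals, agreement with published F statistics is bounded at roughly the
0.5% level for large effects and a few percent for small ones — the
acceptance checks use exactly those bounds.

Pre/post **difference correlations** (`prepost_difference_correlation()`)
correlate per-subject changes in scale scores with changes in microstate
parameters (Pearson, two-sided, Holm across all scale × class × parameter
pairs). Pairs with fewer than 3 finite paired differences are reported as
`NA` rather than fabricated.

### Calibration and power

The mixed 2 (cue) × 3 (group) design is validated by simulation at the
package's scaled-down cohort sizes (10/12/15 subjects): under the null the
interaction's type-I error must stay within [0.03, 0.07] at α = 0.05 over
500 replicates; with a planted cue × group interaction the rejection rate
must reach 80%. The planted effect for the power check is a +65 ms
negative-cue shift of the self-injury group's class-duration response,
sized by a noncentral-F power analysis (difference noise √2·30 ms, groups
10/12/15 → noncentrality ≈ 21, analytic power ≈ 0.98) so the experiment
tests the machinery rather than teetering at the threshold.

## 5. The pipeline

`run_cross_sectional()` / `run_longitudinal()` chain the stages — simulate,
preprocess, fit one shared template, backfit, extract parameters, run the
designs — from a single `run_config()`. One master seed fans out to fixed
per-stage child seeds, so runs are reproducible end to end; output tables
embed an MD5 hash of the configuration (minus the output directory) in their
header line, and byte-identical reruns under a fixed seed are an acceptance
check.

**Shared template.** The template is fit on the sample-wise concatenation
(stacking) of all subject × cell ERPs, then backfitted per cell, so class
indices are comparable across groups, cues and times. Stacking, not
grand-averaging, is used deliberately: averaging subjects' ERPs only
preserves topographic structure if all subjects traverse the same state
sequence in lockstep, and enforcing such a shared sequence in the generator
provably biases the planted coverages (the bias was measured at ~0.03–0.05
before the design was changed). Stacking needs no alignment assumption at
all — each subject's samples enter the clustering as they are. Whether the
motivating study matched per-condition clusters by eye or used one template
is not stated in its methods; the shared template is this package's choice.

**Problem sizes.** The default configuration is a deliberately scaled-down
replica — 10/12/15 subjects (8/7 per arm longitudinally), 30 trials per cue,
600-sample epochs, 20 restarts — chosen so a full run completes in minutes on
one CPU; `paper_scale = TRUE` switches to the published 138-subject design
(labels-only ground truth is practical at that scale, full EEG generation is
memory-hungry). Validation experiments use: 12 s of data for 6-map recovery,
4.8 s × 20 replicates for class-count selection, 500/200 replicates for
calibration/power, and a 13-subject run for determinism.

## 6. Known limitations

* The simulator's white sensor noise understates the spatial correlation of
  real EEG noise; recovery thresholds met here say nothing about recordings
  with correlated artifacts.
* Microstate syntax (transition matrices, Markov tests) and source
  localization are out of scope, as are linear mixed-effects reformulations
  of the designs.
* The occurrence convention is genuinely ambiguous across toolboxes; both
  conventions are implemented, but cross-study comparisons of occurrence
  values should check which one a published table used.
* `mixed_anova()` requires balanced within-subject cells (listwise removal
  otherwise) — the classical repeated-measures frame, not a missing-data
  model.
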