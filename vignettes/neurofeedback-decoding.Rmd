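---
title: "Decoded neurofeedback in silico: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoded neurofeedback in silico: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtnf)
```

`rtnf` implements the full analysis stack of a two-class decoded
neurofeedback experiment — protocol, online preprocessing, SVM decoding,
feedback mapping, group statistics, and the offline GLM — together with a
closed-loop generative model of the subject, so that every stage can be
exercised and tested without access to scanner data.  This vignette is the
package's own account of the underlying models, the parameters that
matter, and the places where the design was genuinely open.

## The experiment being modelled

Each run is a long block design: four tenderness/affection and four pride
blocks of 22 volumes (TR = 2 s), each preceded by a 15-volume neutral
block used for disengagement and signal normalisation — 296 volumes per
run, strictly alternating conditions (`make_default_design()`).  Whether
tenderness or pride comes first is a per-subject argument; the cohort
simulator counterbalances it.  The first two volumes of every block are
excluded from decoding while the haemodynamic response stabilises, leaving
80 usable volumes per emotional condition per run (`label_volumes()`).

Run 1 trains the decoder; during each later run the decoder trained on the
immediately preceding run (`retrain_schedule()`) classifies every usable
volume in real time.  The decision value is mapped to a ring stimulus with
20 distortion levels (`map_level()`): level 1 (fully distorted) signals
misclassification, levels 2–20 quantise the signed distance toward the
target condition, saturating at a distance `d_max`.  Control subjects see
seeded uniform-random levels (`random_stream()`).

## The synthetic subject

`simulate_run()` generates voxel time series on a 24 × 24 × 12 grid of
3 mm voxels (a desk-scale stand-in for a 64 × 64 × 22 EPI matrix; all
algorithms are resolution-agnostic):

```
data(v, t) = 100
           + amp_c * pattern_c(v) * (HRF ∗ boxcar_c)(t)
           + drift_slope * t
           + AR(1) noise, marginal SD sigma
```

* `pattern_c` — two disjoint ellipsoidal activation signatures inside a
  larger ellipsoidal feature mask (`make_atlas()`), with smooth radial
  falloff and seeded multiplicative jitter.  On the default grid the mask
  has ~2600 voxels, each pattern ~100, and a ~60-voxel "small-volume" ROI
  overlaps the tenderness pattern, echoing the few-dozen-voxel a-priori
  basal-forebrain ROIs used in this literature.
* HRF — the canonical double-gamma (response gamma peaking at 5–6 s,
  1/6-amplitude undershoot gamma at ~16 s, 32 s support, continuous-time
  peak normalised to 1), shared between the generator and the GLM
  (`hrf_kernel()`).
* Noise — AR(1) in time (default φ = 0.3) with marginal SD σ, plus a
  linear drift (default 0.02 signal units/volume on a baseline of 100),
  standard minimal fMRI noise structure.  Cardiac/respiratory noise,
  susceptibility dropout and rich head motion are *not* modelled; passing
  tests therefore demonstrates correctness of the pipeline under its own
  assumptions, not robustness to every artifact of real data.

### The learning rule

The feedback-dependent effect is modelled as amplitude gain, not pattern
change: after each feedback run, a contingently-fed-back subject updates

```
amp_tenderness <- max(0, amp_tenderness + eta * (mean_level - 10.5) / 9.5)
```

where `mean_level` is the mean ring level over the run's tenderness
volumes (`update_state()`).  Above-midpoint feedback reinforces the
target pattern, below-midpoint feedback weakens it, and control subjects
never update.  Aggregating feedback per run (rather than per volume)
keeps the toy dynamics stable; the rule intentionally admits both virtuous
and vicious circles — a subject whose amplitude collapses to the floor
decodes at chance thereafter, the in-silico analogue of the occasional
participant whose classification inverts.

### Calibration of the defaults

The literature gives no quantitative learning model, so the generator's
defaults were calibrated once so that a default cohort lands near the
reported group accuracies, and then frozen; they are a working point, not
ground truth.  With `amp = 0.6`, `sigma = 5`, `eta = 2` and feedback
saturation `d_max = 0.08`, the default 12 + 12 cohort at seed 1 yields an
NFB last-minus-first improvement of +14.6 % (SD 12.6), an NFB last-session
accuracy of 74.8 %, a CTR change of −9.8 %, and a between-group t of
−3.78 — the qualitative group × session dissociation with magnitudes close
to the reported ones.

One interaction deserves emphasis.  `feedback_config()` defaults to
`d_max = 1`, the canonical margin of the decoder's support vectors — the
natural choice when one thinks of decision values on the training set.
But decision values of *unseen* volumes shrink toward the boundary
(average |d| ≈ 0.3 at realistic noise), so with `d_max = 1` the mean ring
level sits far below the update rule's midpoint at any attainable accuracy
and amplitudes could only decay.  The cohort simulator therefore uses a
saturation distance matched to the test-volume decision-value scale
(`d_max = 0.08`) as part of the study conditions.  Users changing the
noise level should expect to revisit this constant.

## Online preprocessing

Volumes pass through (optional) translation-only realignment, 6 mm-FWHM
separable Gaussian smoothing, and neutral-baseline subtraction, in that
order (`preprocess_run()`).  Numerical choices:

* Smoothing kernels are truncated at 4 SD and renormalised rowwise, so
  constant fields are preserved exactly, including at lattice boundaries,
  and `fwhm = 0` is the identity.
* Realignment (off by default; the generator is motion-free) estimates
  the integer-voxel translation maximising cross-correlation, refines it
  per axis by quadratic interpolation of the correlation peak, and
  resamples trilinearly.  Full 6-DOF rigid realignment is out of scope;
  the translation-only version preserves the contract (align to a
  reference EPI) at desk scale.  A peak correlation below 0.2 flags the
  estimate as low-confidence.
* The normalisation baseline is the voxelwise mean of the most recent
  *completed* neutral block — the pipeline is causal by construction, and
  the run-initial neutral block (guaranteed by the design validator)
  serves the first emotional block.
* Feature vectors are `(volume − baseline)` at mask voxels in the grid's
  native order (x fastest); the ordering is fixed and shared with the
  decoder's weight vector, so train and decode always agree.

## Decoder

Training solves the standard two-class soft-margin linear SVM (via the
libsvm solver) and stores the explicit hyperplane `(w, b)`, oriented so
positive decision values are the tenderness side.  Defaults follow what
the method descriptions leave open: `C = 1`, no feature standardisation
beyond the neutral-baseline subtraction, unregularised intercept as
provided by the solver; all configurable.  An exact-zero decision value
classifies as pride, so tenderness-classified counts are conservative.
Discriminant maps rank voxels by |w|; the flagged count is
`round(fraction × n)` (half away from zero) with |w| ties broken by voxel
order, making the 2 % maps deterministic.  Tests verify the trained
hyperplane against a brute-force hard-margin search on small 2D instances,
the margin-equals-one property, and scaling covariance.

## Group statistics

`pct_tenderness()` is the share of usable tenderness-condition volumes
classified as tenderness; "trials" are volumes, because the per-subject
above-chance criterion (accuracy > 60 % significant at p < .05 by exact
binomial test) is only meaningful with per-volume counts (n = 80;
`binomial_exact(48, 80)` = 0.046).  Within-group change and last-session
tests are one-sample Student t tests; the between-group test is the
pooled-variance two-sample t (df = n₁ + n₂ − 2 = 22 for 12 + 12), matching
the reported degrees of freedom.  Per-subject accuracy is taken from the
last classification session only.  `cohort_report()` assembles the panel
and degrades explicitly (notes instead of statistics) for single-subject
groups or zero-variance outcomes.

## Offline GLM and small-volume correction

The first-level design (`build_design()`) convolves full-block boxcars for
all three conditions with the canonical HRF and adds an intercept plus
high-pass drift regressors for the 448 s cutoff.  The drift set is the
standard DCT basis — `floor(2 · T · TR / cutoff)` = 2 columns here — *plus
an explicit linear trend*: two cosines alone only approximate a ramp, and
the residual would leak asymmetrically into the condition regressors
(≈ 0.8 contrast units per 0.3 units/volume of drift on this design).  With
the linear term, linear scanner drift is removed exactly, which the tests
assert at 1e−6.  Estimation is voxelwise OLS (prewhitening is unnecessary
for the parameter-recovery properties tested here, where OLS is unbiased);
the contrast is tenderness − pride.

The second level regresses subject contrast maps on the per-subject
covariate (last-minus-first change in percent tenderness classification)
and FWE-corrects within an a-priori ROI by max-statistic permutation
(`svc_correct()`): the covariate is permuted (seeded), the ROI maximum |t|
recomputed each time, and the corrected p is the observed peak's rank,
`(1 + #{max ≥ peak}) / (n_perm + 1)`.  This replaces random-field-theory
SVC, whose smoothness estimation is heavy and opaque at desk scale;
permutation gives exact FWE control for exchangeable covariates, which the
tests verify by null calibration (rejection rate at α = 0.05 within
[0.02, 0.08] over 200 simulations).  Cluster size is reported for the
suprathreshold component containing the peak at the conventional p < .005
(one-sided) forming threshold, with 6-connectivity.

## Problem sizes used by the test suite

The suite runs entirely on synthetic data built at test time: unit tests
mostly use a 12 × 12 × 6 grid, the end-to-end dissociation check runs the
full default cohort (24 subjects × 4 runs × 296 volumes at 24 × 24 × 12,
about a minute), and the null-calibration experiment uses 200 simulated
datasets with 199 permutations each.  These sizes were chosen so the whole
suite completes in a few minutes while keeping every statistical check
adequately powered.

## Known limitations

* The learning model is a deliberately minimal amplitude-gain rule; it
  reproduces the direction and rough size of the group × session effect,
  not individual learning curves.
* Simulated noise omits physiological components and motion (beyond the
  optional translation injection), so realignment is exercised only on
  constructed shifts.
* Whole-brain random-field FWE, anatomical normalisation to a standard
  space, and behavioural questionnaire analyses are out of scope.
* The control group's slight negative drift in the worked example is
  sampling variability, not a modelled disengagement effect.
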