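---
title: "Methods: comparing rapid and standard structural scans with rapidvol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing rapid and standard structural scans with rapidvol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rapidvol)
```

## The problem

Ultra-fast multicontrast MR sequences can acquire a T1-weighted contrast in
about a minute, at the cost of lower signal-to-noise and a reduced axial
field of view (FoV). Before such scans can feed quantitative pipelines, two
questions must be answered: do tissue-volume estimates (grey matter, white
matter, CSF — GM/WM/CSF) agree with those from a standard high-resolution
T1-weighted scan, and do downstream summary measures such as predicted
brain-age survive the switch? `rapidvol` implements the statistical
machinery for that comparison:

* global and voxel-wise tissue volumetrics with a participant-coverage
  inclusion mask;
* Spearman/Pearson association summaries and a paired bootstrap test for
  differences in correlation strength;
* ICC(3,1) test-retest reliability with F-based confidence intervals;
* brain-age evaluation (median absolute error, a constant-prediction null
  benchmark, and leave-one-out regression correction of systematic offsets);
* a compact Gaussian-process (GP) age model used to demonstrate *why* a
  truncated FoV produces systematically offset brain-age predictions.

Because raw scans cannot ship with a package, a synthetic cohort generator
produces paired "segmented" tissue-volume maps with the statistical
structure the analysis assumes. The generator is first-class, tested code:
every pipeline stage runs end-to-end on it.

## The synthetic cohort

### Cohort

Ages are drawn from a normal distribution with mean 28.2 y and SD 9.2 y,
truncated to [18, 59] by rejection sampling — the three printed summaries
(mean, SD, range) of the population the package emulates determine the
distribution up to the choice of truncation mechanism, and truncation is the
simplest member of that family. The default cohort has 64 participants, the
first 10 of whom receive a second, within-session rapid acquisition.

### Tissue maps

The phantom lives on a 24 × 24 × 16 grid of 4 × 4 × 6 mm voxels — large
enough to have an axial axis worth truncating, small enough that a 2000-
participant cohort generates in well under a minute. Each tissue class has a
noise-free template: WM is a compact central blob, GM a cortical shell
elongated axially so that it alone reaches the slices removed by FoV
truncation (the empirical situation: truncation clips cortex), and CSF is
mostly a concentrated "ventricle" blob plus a thin outer sheet that stays
inside the truncated FoV. Templates are scaled to total volumes of 250,000
(GM), 200,000 (WM) and 120,000 (CSF) mm^3 — desk-scale stand-ins with
realistic proportions.

Participant $i$'s latent map for a tissue with template $t(v)$ is

$$\ell_i(v) = t(v)\,\Bigl(1 + \frac{b_i + \beta_{\mathrm{age}}
(\mathrm{age}_i - \bar{a})}{V}\Bigr),$$

where $V = \sum_v t(v)$, $b_i \sim N(0, (\mathrm{cv}\cdot V)^2)$ is a
participant random effect (default cv = 0.025), and the age term applies to
GM only ($\beta_{\mathrm{age}} = -350$ mm^3/y by default). The study the
package emulates reports GM–age rank correlations of about −0.28 to −0.44
but no slope; the default slope places the simulated correlation between
those two values and is documented here rather than calibrated.

### Measurement error and the correlation targets

The standard-sequence map adds measurement error to the latent map; the
rapid sequence adds a larger error. Error variances are solved *exactly* at
the global-volume level from the configured cross-sequence correlation
targets (defaults 0.84/0.84/0.56 for GM/WM/CSF): writing $v_\ell$ for the
latent variance of global volume, $a v_\ell$ for the standard noise variance
and $k a v_\ell$ for the rapid noise variance (with noise ratio $k = 2$),

$$\rho = \frac{1}{\sqrt{(1 + a)(1 + k a)}}$$

is inverted for $a$ in closed form. `tissue_variance_components()` exposes
the full decomposition.

How that global variance is *realised* across voxels matters. If the noise
were spread as independent per-voxel draws, each voxel's noise SD would
exceed the per-voxel between-participant signal by roughly
$\sqrt{n_\mathrm{eff}}$ (with $n_\mathrm{eff} = (\sum_v t)^2 / \sum_v t^2$
the template's effective support, several hundred to a thousand voxels
here): voxel-wise cross-sequence correlations would collapse to ~0 and the
non-negativity clamp would truncate heavily, breaking the solved global
algebra. Real cross-sequence disagreement is not white voxel noise — it is
dominated by participant-level differences in segmentation and scaling that
move a whole map coherently. Each error source is therefore drawn as

* a **participant-level multiplicative term** proportional to the template,
  carrying a fraction $1 - s$ of the variance, plus
* **independent per-voxel noise** with SD proportional to the template
  value, carrying the remaining share $s$ (`voxel_noise_share`, default
  0.001).

The split is invisible at the global-volume level, so the solved correlation
targets hold exactly in expectation, while the voxel-level error variance is
amplified by $\mu = (1 - s) + s\,n_\mathrm{eff}$ relative to the signal.
Expected voxel-wise correlations are then
$v_\ell / \sqrt{(v_\ell + \mu a v_\ell)(v_\ell + \mu k a v_\ell)}$ — at the
defaults about 0.69 (GM), 0.79 (WM) and 0.53 (CSF), below the global targets
and ordered by template concentration, which is the empirically observed
pattern. With the default share, voxel values stay far from zero and the
clamp at 0 is inactive in practice.

### Retest structure

A within-session retest cannot be "latent plus fresh noise at the full
rapid-sequence level": with the rapid noise solved from a cross-sequence
correlation of 0.84, that would cap the attainable retest ICC near 0.87,
whereas rapid sequences empirically show global ICCs near 0.99 *and*
cross-sequence correlations near 0.84 simultaneously. Those two facts
jointly require most of the rapid sequence's deviation from the standard
sequence to be stable within a session. The generator therefore splits the
rapid error into a stable component and per-acquisition noise with global SD
`retest_noise_sd` (default 750 mm^3); a retest scan redraws only the
latter. The expected retest consistency is
$(v_\ell + v_b)/(v_\ell + v_b + v_e)$ — about 0.990/0.982/0.970 for
GM/WM/CSF at the defaults — and is exposed by
`tissue_variance_components()`, which the recovery tests check against.

### Smoothing and field of view

Rapid-sequence maps are smoothed with a separable Gaussian kernel at 4 mm
full width at half maximum ($\sigma = \mathrm{FWHM}/2.355$ per axis,
truncated at $4\sigma$, never narrower than one voxel). The kernel is
**mass-preserving**: every source voxel redistributes its tissue volume with
weights renormalised to sum to one, including at grid boundaries, so each
participant's global volume is exactly invariant under smoothing — tissue
volume is a conserved quantity, and this keeps the global correlation
targets exact.

The reduced FoV is emulated as symmetric axial truncation
(`fov_drop_slices` = 2 of 16 slices at each extreme), recorded as an
explicit boolean mask so volumetrics can treat it exactly; about 13% of the
GM template (and almost none of WM/CSF) lies in the dropped slices. Because
every map component scales with the template, truncation acts
multiplicatively per participant and leaves the cross-sequence correlation
essentially unchanged — consistent with the empirical observation that
global agreement survives FoV reduction.

### Brain-age predictions

Simulated prediction tables use `pred = age + noise` (SD 5.5 y) for the
standard sequence, an affine distortion `26 + 0.6 × age + noise` for the
rapid sequence, and `31 + 0.35 × age + noise(7)` for the reduced-FoV
standard scans. The rapid parameters were chosen so the median absolute
error is on the order of 14 y while the rank correlation with age stays
around 0.6 — the qualitative signature being emulated: high correlation,
large systematic offset.

## Statistical choices

**Spearman correlation.** Pearson correlation of average ranks (ties get the
mean rank); the two-sided p-value uses
$t = r_s\sqrt{(n-2)/(1-r_s^2)}$ with $n-2$ degrees of freedom. An exact
permutation p is unnecessary at the sample sizes involved; $|r_s| = 1$
reports the limiting value 0.

**Bootstrap difference in association strength.** Within each replicate the
*same* resampled participant indices apply to every contrast, so the
difference distribution is paired — without this the difference in two
nearly identical associations would be buried in independent resampling
noise. Intervals are percentile (2.5th/97.5th points of the 10,000-replicate
difference distribution by default). Replicates in which any statistic is
undefined (a constant resample) are redrawn rather than dropped, keeping
exactly `n_boot` replicates; the redraw count is reported.

**ICC.** The implemented default is the two-way consistency form for single
measurements, ICC(3,1): $(MS_B - MS_E)/(MS_B + (k-1)MS_E)$, invariant to an
additive shift between scans. The literature's labels for one-way versus
two-way forms are frequently conflated; the "(3,1)"/"consistency"
designation is taken as operative, with the one-way ICC(1,1) available via
`model = "one-way"`. Confidence limits come from the F statistic
$MS_B/MS_E$ with $(n-1)$ and $(n-1)(k-1)$ degrees of freedom.

**Error metric.** "MAE" here is the *median* of absolute errors (robust to
exactly the systematic offsets under study); the mean is an option. All
medians and quartiles in the package use linear interpolation between order
statistics (R's type-7 quantile), recorded so oracle tests can reproduce
every summary bit for bit.

**Inclusion mask.** A voxel enters voxel-wise analyses when at least 95% of
participants show at least 0.001 mm^3 of tissue there; "at least 95%" is
implemented as `count >= ceiling(0.95 n)` — the conservative reading of a
fractional participant count — and the threshold comparison is `>=`.
Zero-variance voxels yield missing correlations (not 0) and are excluded
from distribution summaries.

**Leave-one-out offset correction.** For each participant, ordinary least
squares regresses the standard-sequence prediction on the rapid-sequence
prediction over the other $n-1$ participants; the left-out prediction is
mapped through the fitted line. The fit is plain univariate OLS (computed by
down-dated sums, checked against a from-scratch normal-equations oracle); no
robust or weighted variants.

## The GP stand-in and the FoV experiment

The pre-trained brain-age model being emulated is out of reach (thousands of
external training scans), so `gpr_fit()` provides a small GP regression with
a squared-exponential kernel on standardised volumetric features: the three
global tissue volumes plus eight octant GM sums — few enough to be
desk-scale, spatially coarse enough to be FoV-sensitive. The posterior mean
is computed about a prior mean equal to the mean training age, so queries
far from the training distribution revert to it, as GP regressions do.

The default length scale (30 on the standardised feature scale) deliberately
keeps the model in a near-linear regime. This is a design decision with a
visible alternative: with a short length scale, truncated-FoV features move
many length scales away from the training cloud and predictions collapse to
the prior mean — a *different* failure mode (constant predictions) from the
one under study (a graded systematic offset that preserves the correlation
with age). The long length scale reproduces the offset mechanism: features
computed after `reduce_fov()` are missing tissue the model expects, so
predictions shift coherently while their ordering is preserved.

`fov_offset_experiment()` trains the GP on full-FoV features of one
generated cohort (default 200 participants), predicts on a second cohort
from full-FoV and truncated-FoV features, and applies the leave-one-out
regression of the full-FoV predictions on the truncated ones. The
acceptance suite checks the directional claims — truncation raises the
error, the regression adjustment lowers it back — on five consecutive seeds.

## Problem sizes and numerical tolerances in the test suite

* Generator recovery: cross-sequence correlations are checked at $n = 2000$
  participants against the configured targets within ±0.02; since a single
  cohort's empirical correlation has sampling SD ≈ 0.007, the estimate is
  averaged over three independent cohorts of that size. Retest ICC is
  checked at $n_\mathrm{retest} = 200$ against the variance-ratio implied by
  the configuration, within ±0.02; the GM–age correlation is checked for
  sign on ten seeds at $n = 200$.
* Bootstrap calibration: 500 outer replications of a null construction (two
  contrasts with identical population correlation with age, $n = 64$) at
  1000 bootstrap replicates each; the 95% interval must cover zero in
  95% ± 2.5% of replications.
* Oracle equivalences (ICC vs. loop ANOVA, quantiles vs. sort-and-index,
  LOO folds vs. normal equations, GP vs. hand-coded elimination) are exact
  to between 1e-8 and 1e-12.
* The >= 0 clamp, smoothing mass preservation and FoV monotonicity are
  property-tested on small grids where brute-force enumeration is feasible.

## What the synthetic cohort does and does not show

The generator reproduces the *statistical* structure the analysis consumes:
paired sequences with tissue-specific agreement, an age-declining GM signal,
stable-plus-acquisition retest structure, axial truncation, and offset
brain-age predictions. It does not attempt realistic anatomy (no atlas
templates), spatially varying noise, bias fields, motion, registration
error, or spatial autocorrelation beyond the smoothing kernel; voxel-level
agreement is near-uniform inside each template rather than regionally
structured as in real maps. Passing tests therefore validate the
*estimators and pipeline plumbing* — that correlations, ICCs, bootstrap
intervals, error metrics and corrections measure what they claim under a
known ground truth — not the empirical performance of any particular
acquisition. One visible consequence: the constant-prediction null error of
the synthetic cohort (~9.5 y) is smaller than published values for real
cohorts with strongly young-skewed age distributions, so null-benchmark
ratios computed on synthetic data are systematically smaller than published
ones even when the model errors match.

## Reproducibility

Every source of randomness derives from a single integer seed: the
generator stages use fixed per-stage offsets from `config$seed` (so a stage
can be rerun in isolation), the pipeline's bootstrap uses `seed + 4`, and
the FoV experiment derives its training and test cohort seeds as
`seed + 10` and `seed + 20`. Identical configurations yield bit-identical
reports, which the suite asserts.
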