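---
title: "Benchmarking physiological denoising for fast-TR resting-state fMRI: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking physiological denoising for fast-TR rs-fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denoisebench)
```

## The problem

Cardiac pulsation (~1 Hz) and respiration (~0.3 Hz) are major nuisance
contributions to resting-state BOLD fMRI.  At conventional sampling
(TR ≈ 2 s) these oscillations alias into the 0.01–0.1 Hz band that carries
most functional-connectivity information, so the amount of physiological
power a denoising method removes cannot be measured directly.  Fast
simultaneous-multi-slice acquisitions (TR ≈ 0.38 s, Nyquist ≈ 1.3 Hz) sample
the cardiac fundamental directly, which makes the question quantifiable:
how much power does each data-driven denoising method remove in the cardiac,
respiratory and low-frequency bands, and what does that do to
functional-connectivity metrics and to detectable differences between age
groups?

`denoisebench` implements that comparison end to end on synthetic data with
full ground-truth bookkeeping: a cohort generator, five data-driven
denoising methods plus a no-correction baseline, band-resolved spectral
power accounting, connectivity metrics, mixed-model group statistics, and a
decimation experiment that reintroduces aliasing on purpose.

## The synthetic cohort generator

`generate_cohort()` draws two groups (default 18 young, 18 old) of subjects
with 1950 volumes at TR = 0.38 s on a 16×16×10 voxel grid.  Tissue is
assigned concentrically on an ellipsoidal "brain": a CSF core (ventricles),
a WM shell, a GM ribbon, and an outer CSF layer; everything else is
background.  GM is subdivided into 200 ROIs grouped into 7 networks.

Each voxel's series is a weighted sum of unit-variance component courses
plus white noise, with the weight of component $c$ in voxel $v$ equal to
$\sqrt{f_c(v)}\,\sigma$, so that each component contributes exactly the
fraction $f_c(v)$ of the voxel's variance.  The realized per-voxel fractions
are stored in the ground truth and drive the parameter-recovery validation.

* **Neural signal** — per-network Gaussian processes band-limited to
  0.01–0.1 Hz; ROI courses mix the network course with ROI-specific
  innovations so that two ROIs of the same network correlate at the
  configured coupling (default 0.5 in young subjects).
* **Cardiac and respiratory oscillations** — amplitude-modulated sinusoids
  with one harmonic.  The per-subject frequencies are drawn once from
  truncated normals (cardiac N(1.0, 0.1) Hz on [0.6, 1.5]; respiratory
  N(0.27, 0.04) Hz on [0.15, 0.4], matching typical adult physiology) and
  used both in the BOLD mixture and in the simulated high-rate
  physiological recording.  Each voxel oscillates with its own phase,
  implemented by mixing a quadrature basis
  $\{a(t)\sin\omega t,\; a(t)\cos\omega t,\; a(t)\sin 2\omega t,\;
  a(t)\cos 2\omega t\}$ with coefficients normalized per voxel to exact
  unit variance.  The phase dispersion emulates spatially varying
  pulse-wave/respiratory arrival times; without it every nuisance source
  would share one spatial pattern, the noise-ROI covariance would be
  rank-one, and principal-component methods could not behave as they do on
  real data.  Cardiac variance is boosted in CSF (×3) and in a small
  fraction (5%) of vessel-like GM voxels, giving the anatomically informed
  methods something structured to capture.
* **Global nuisance** — one low-frequency (< 0.1 Hz) course shared by all
  in-brain voxels with uniform weight, the target of global-signal
  regression.
* **Drift** — a slow trend with per-voxel random sign.
* **Motion** — a six-parameter random walk with occasional spikes is always
  generated; by default it is *not* injected into the BOLD data (the
  benchmark isolates physiological denoising and no method receives motion
  regressors), but `motion_artifact = TRUE` adds a motion-locked rim
  artifact for classifier validation.

### The aging effect is regionally specific

Old subjects lose within-network coupling (default 0.5 → 0.3) only in a
fixed 40% subset of each network's ROIs (`age_effect_roi_fraction`).  This
is deliberate: a spatially *uniform* coupling reduction changes only the
amplitude of a subject's connectivity map, and every map-similarity measure
used downstream (cosine similarity, and hence the age-partition modularity)
is scale invariant, so a uniform effect would be mathematically invisible.
Regionally concentrated age differences are also what aging studies report.
The mean young coupling still exceeds the mean old coupling, which the
group-structure tests verify.

### What the generator does not emulate

No hemodynamic response function, no susceptibility or slice-timing
artifacts, no spatial autocorrelation of the noise, no non-stationarity
beyond slow amplitude modulation of the oscillators, and no systematic
tSNR difference between groups unless the `old_noise_scale` knob is turned.
Passing tests therefore demonstrate internal consistency of the methods
under a known generative model, not performance on scanner data.

## Preprocessing

The common preprocessing is intentionally minimal: discrete-cosine
high-pass regression (cutoff 0.01 Hz; a projection, hence idempotent and
phase-neutral — an IIR filter would distort phases differently across the
band), optional volume-wise Gaussian smoothing (FWHM in mm), Power-style
framewise displacement (rotations converted on a 50 mm sphere), and tSNR
maps with zero-variance voxels flagged rather than made infinite.

Mask erosion for the WM/CSF-based methods uses an in-plane (4-neighbour)
structuring element by default: on this grid the tissue shells are about
one voxel thick along the slice axis — as they are on thick-slice
acquisitions — and a full 6-neighbour erosion would empty them.  The
6-neighbour element is available via `axes = 1:3`.

## The denoising methods

* **GSR** — mean course over brain-minus-CSF voxels.
* **WM-CSF** — mean courses over eroded WM and eroded CSF masks.
* **aCompCor** — five leading principal components of the variance-normalized
  voxel×time matrix on the combined eroded WM+CSF mask (a per-tissue variant
  is available).  Five components is the conventional default.
* **tCompCor** — components from the voxels above the 98th percentile of
  temporal standard deviation regardless of tissue, keeping components up to
  50% cumulative explained variance; all returned components are removed.
  Both thresholds are exposed.
* **AROMA-like ICA** — spatial ICA (symmetric FastICA, tanh contrast,
  written in-package) followed by the four canonical motion/physiology
  features: maximum absolute correlation with the motion parameters and
  their derivatives, high-frequency content (the fraction of the Nyquist
  range above which half the spectral power lies), brain-edge weight
  fraction, and CSF weight fraction.  A component is noise if CSF fraction
  > 0.10, or high-frequency content > 0.35 (the canonical thresholds), or
  if (motion correlation, edge fraction) falls outside the line with axis
  intercepts 0.8 and 0.85.  This is an AROMA-*like* classifier, not a
  bit-exact port: there is no MELODIC and no trained hyperplane.  Removal is
  non-aggressive by default: all component courses are fitted jointly and
  only the noise-classified contribution is subtracted.  Numerical note:
  PCA directions at the white-noise eigenvalue floor (eigenvalue below
  twice the upper-quartile eigenvalue) are dropped before the ICA rotation —
  independence is undefined in that subspace and the symmetric iteration
  oscillates without settling; the ICA seed is fixed and recorded.
* **none** — the baseline; regression with an intercept only.

Aggressive removal is the per-voxel OLS residual; residuals are orthogonal
to every removed regressor, and per-voxel variance can only decrease.
Collinear design columns are dropped with a warning.

## Spectral evaluation

Band definitions follow the subject: a 0.1 Hz-wide band centred on the
subject's cardiac frequency, a 0.2 Hz-wide band on the respiratory
frequency, and the fixed 0.01–0.1 Hz low band.  The subject frequencies are
estimated from the peak of the physiological-recording periodogram within a
search band; the confidence flag compares a *smoothed* spectrum's peak
against three times its median, because the raw maximum of hundreds of
exponential-like periodogram bins exceeds any fixed multiple of the median
even for white noise.

Tissue spectra average the time series over the mask *first* and then take
the periodogram of that mean course (the alternative — averaging individual
voxel spectra — is a different estimator: it retains the full noise floor,
whereas averaging first suppresses independent noise by the mask size).
The periodogram uses a Hann taper by default, with power normalized by the
taper energy so that the integral of the density equals the taper-weighted
variance exactly (the plain variance when `taper = "none"`); this keeps the
Parseval identity a testable invariant while retaining leakage suppression.
Band power is the sum of density times bin width over bins whose centres
fall in the band; whether one integrates density or sums raw periodogram
bins cancels in the fractional power change
$(P_\mathrm{unc}-P_\mathrm{cor})/P_\mathrm{unc}$, which is scale invariant.

`alias_frequency(f, fs)` folds any frequency into $[0, f_s/2]$ and predicts
where decimated oscillations land; decimation (`downsample()`) deliberately
applies no anti-alias filter because aliasing is the phenomenon under
study.

## Connectivity metrics

**Template-based rotation.**  Stage 1 predicts each network template as a
linear sum of the data volumes by least squares over voxels; stage 2
reports the per-voxel t statistic against the stage-1 course.  On this
package's scaled grids the in-brain voxel count (~1000) is *below* the
volume count (1950), a regime real acquisitions never reach; unpenalized
stage 1 then interpolates any template exactly through voxel noise and the
t-maps degenerate into template copies.  Stage 1 therefore applies a ridge
penalty (default: the mean diagonal of the volumes' Gram matrix) whenever
voxels ≤ volumes, which keeps the estimator near the template-weighted
mean-course regime; the penalty is recorded on the result.  The t-maps are
invariant to template scaling.

**ROI metrics.**  Pearson correlation matrices over ROI-mean courses; the
network-mean correlation averages unique within-network pairs; the
functional-connectivity contrast (FCC) is the tie-corrected
normal-approximation rank-sum z comparing within-network against
between-network pair values, averaged over the seven networks.  A fully
tied comparison returns z = 0.

**Age-partition modularity.**  For each network, subject maps are compared
with cosine similarity and the fixed young/old split is scored with the
Newman-style quality
$Q = \frac{1}{4m}\sum_{ij}\left(A_{ij}-\frac{k_ik_j}{2m}\right)s_is_j$,
computed as the literal double sum with zero diagonal.  `modularity()`
defaults to the raw similarity values; the pipeline's cohort-level
computation first centres the maps on the cohort mean and clips negative
similarities to zero (the configuration null model assumes nonnegative
weights).  The centring resolves a genuinely open design point: raw
connectivity maps share the network geometry itself, so their pairwise
cosines are all close to one and carry almost no between-subject
information; similarity of *deviations* from the cohort mean is what
separates the groups.  Both behaviours are exposed and tested.

## Group statistics

The band-power ANOVA is a Gaussian linear mixed model with fixed effects
for age group, tissue, method and the age×method interaction and a
subject-level random intercept, one frequency band at a time; the
connectivity ANOVA uses age (between) and method (within).  Fits use
`nlme::lme` with its inner–outer (containment) denominator degrees of
freedom; `ddf = "satterthwaite"` switches to `lmerTest`.  The reported
table is the sequential decomposition, which for these balanced designs is
the classical mixed-ANOVA table (a marginal decomposition under treatment
contrasts would test simple effects at the reference level and lose
power).  Designs with one observation per subject reduce automatically to
fixed-effects ANOVA.  Follow-up comparisons are paired t-tests between
methods and unpaired t-tests between groups, Benjamini–Hochberg corrected
within each family (per band and tissue for power; per metric for
connectivity).

Calibration is part of the deliverable: `anova_calibration()` simulates
null and effect datasets at the study size (two groups of 18, five
methods, two tissues) and reports per-factor type-I rates at α = 0.05 and
detection rates for a one-noise-SD method effect (at p < 0.01) and a
1.5-subject-SD age effect (at p < 0.05).

## Validation against ground truth

Three recovery checks anchor the pipeline to the generator's bookkeeping
(they consume ground truth; the pipeline itself never does):

* regressing the true cardiac quadrature courses out of the raw data must
  remove cardiac-band power equal to the injected per-voxel cardiac
  variance fraction (grey-matter mean, 15% relative tolerance).  The
  removed power is referenced to the voxel's *total* variance because the
  cardiac band also holds a white-noise floor that regression rightly
  leaves in place;
* aCompCor must recover two planted orthogonal mask sources at |r| > 0.95
  on a constructed instance (on the full cohort, individual components mix
  sources that share spatial weight patterns — a rotational ambiguity — so
  cohort-level recovery is reported as the multiple correlation with the
  component span);
* the component classifier must label planted 1 Hz, motion-locked,
  edge-confined and CSF-confined components as noise and a 0.03 Hz
  network-confined component as signal (`aroma_validation_scene()`).

## Problem sizes

Unit tests run on reduced cohorts (typically 3+3 subjects, 500 volumes, a
12×12×8 grid with 42 ROIs), chosen so the whole unit suite completes in
well under a minute while every contract stays nontrivial.  The acceptance
suite and `scripts/acceptance.R` use the full study-scale configuration —
36 subjects, 1950 volumes, the 16×16×10 grid with 200 ROIs — for parameter
recovery and the direction-of-effect comparisons, 100 random instances for
the regression contracts, 200 replicates for the statistical calibration,
and 1000 permutations for the modularity null.

## Known limitations

The AROMA-like classifier's linear boundary is a package default, not a
trained discriminant; its thresholds are calibrated for this generator's
geometry, where CSF occupies a larger voxel share than in a real brain.
The TBR ridge choice is specific to the voxel-limited regime of the small
grid.  Real-data mode accepts external label volumes and templates but has
only been exercised on synthetic volumes written by the package itself.
Band-power analysis at the decimated rate is not reported (the cardiac and
respiratory bands fold below Nyquist), matching the design of the
downsampling experiment, which compares connectivity metrics only.
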