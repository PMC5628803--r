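---
title: "Methods: band-limited amplitude mapping and cluster-corrected group inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band-limited amplitude mapping and cluster-corrected group inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alffpipe)
```

## What the package computes

`alffpipe` analyses resting-state BOLD series through the amplitude of
low-frequency fluctuations (ALFF): for every voxel, the average one-sided
Fourier amplitude of its time series inside a low-frequency band
(default 0.008–0.09 Hz), normalized by the subject's mean over the brain
mask so that the in-mask mean is 1. Normalized maps are compared across
three groups (`CTL`, `ACTL`, `SCD`) with a voxelwise ANCOVA adjusted for
age, cluster-corrected by Monte-Carlo simulation, followed by post-hoc
two-sample contrasts, a lesion-load subgroup test, and Pearson
correlation of regional mean ALFF with neurocognitive scores under
Benjamini–Hochberg FDR control.

The statistic at voxel $v$ is

$$\mathrm{ALFF}_v = \frac{1}{|K|}\sum_{k \in K} a_k, \qquad
  a_k = \frac{2\,|X_k|}{T},\qquad
  K = \{k : f_{lo} \le k/(T\,\mathrm{TR}) \le f_{hi}\},$$

with $X_k$ the DFT of the detrended voxel series of length $T$. Under
this scaling a pure sinusoid of amplitude $A$ on Fourier bin $k \in K$
contributes exactly $A/|K|$; for $T = 238$, TR = 2 s and the default
band, $K = \{4,\dots,42\}$ (39 bins). At the Nyquist bin of an
even-length series the factor 2 is dropped.

## Detrending that cannot bias the band

Removing a linear drift before the transform is necessary — a ramp leaks
amplitude $\propto 1/k$ into exactly the low bins ALFF averages. But the
ordinary least-squares line of a finite sinusoid is not zero: naive
detrending perturbs a bin-4 sinusoid's recovered amplitude by up to tens
of percent, depending on phase. `compute_alff` therefore estimates the
slope with the in-band Fourier modes partialled out of the time
regressor and removes the fitted line. Two exact properties follow, both
under test:

* a pure ramp is removed completely, including its in-band leakage
  (the slope estimate of a ramp is unchanged by the partialling);
* a pure in-band sinusoid is untouched, so planted amplitudes are
  recovered to machine precision.

A consequence worth knowing: applying the explicit ideal band-pass
filter (`bandpass_filter`) before `compute_alff` is exactly equivalent
on trend-free data, but on drifting data the filter route *keeps* the
drift's in-band leakage that the detrending route removes. The pipeline
therefore computes ALFF directly from the detrended series; the filter
stage exists for fidelity to common practice and is exercised by an
equivalence test on trend-free phantoms.

## The synthetic cohort

All development and calibration runs use a phantom cohort
(`simulate_cohort`): an ellipsoidal brain on a small common grid
(default 24×24×12 voxels of 3 mm, 238 volumes at TR = 2 s) with a
gray-matter shell, a white-matter core, a CSF shell and an out-of-brain
block — the latter three serving as the CompCor noise
regions-of-non-interest. Gray voxels receive `n_oscillators` (default 3)
sinusoids drawn uniformly inside the band, plus baseline, linear drift
(0.01 units/volume) and AR(1) noise (coefficient 0.3, innovation sd 1 at
baseline 100). Noise compartments carry a shared per-subject confound
waveform (one in-band and one respiratory-like component) that CompCor
is expected to recover; a config switch mixes it into gray matter for
end-to-end confound-removal tests. Motion is a clamped Gaussian random
walk over the six rigid-body parameters, with the equivalent affines.

Group effects are planted as multiplicative amplitude factors on
compact 30-voxel regions of the gray shell. Between-subject amplitude
variability is log-normal and **drawn independently per voxel**. This is
deliberate: it makes the phantom's group maps spatially exchangeable
with the independent-noise null, so the cluster correction can be
audited exactly (below). A subject's recorded regional truth is the
realized mean amplitude over the region's voxels; score models couple
neurocognitive scores linearly to that truth.

What the phantom does *not* emulate: anatomy, scanner artifacts,
susceptibility distortion, spatially correlated physiological noise, or
the smooth spatial covariance of real BOLD data. Passing calibration
tests on the phantom therefore shows the machinery is correct under its
stated assumptions, not that real data meet them — with real maps the
null-field FWHM must model the data's actual smoothness.

## Preprocessing chain and its parameters

Stage order: discard (default 2 volumes) → slice-timing correction
(linear interpolation to the mid-TR, sequential ascending order by
default) → motion QC → grand-mean intensity scaling (target 10,000) →
CompCor component extraction → 8 mm FWHM Gaussian smoothing → nuisance
GLM. CompCor components are taken from the *unsmoothed* normalized
series so smoothing cannot mix gray-matter signal into the noise
compartments. The nuisance design has 17 columns: 6 motion parameters,
their backward differences (first row zero), and 5 CompCor components;
an intercept is added internally and voxel means are restored after
regression so ALFF normalization stays well defined. All-constant or
duplicated design columns are pruned with a warning, because motionless
phantoms are legitimate inputs.

Motion QC excludes a subject when the maximum volume-to-reference RMS
displacement exceeds 1.5 mm. The RMS is the closed form over a solid
sphere of radius 80 mm centered at the volume center,
$\sqrt{R^2\,\mathrm{tr}(A^\top A)/5 + \lVert t + A\,x_c\rVert^2}$ for
relative transform $(I + A,\, t)$, verified against Monte-Carlo ball
sampling to $10^{-3}$ mm.

An "8 mm × 8 mm × 8 mm Gaussian kernel" is read as FWHM = 8 mm (the
field's reporting convention); kernels are separable,
isotropic in millimetres (anisotropic voxels handled per axis), with
symmetric boundary handling so constants are preserved.

## Cluster-extent correction

`mc_cluster_threshold` implements the AlphaSim-style correction: fill
the grid with unit Gaussian noise, smooth to the assumed FWHM,
standardize within the mask, threshold at the per-voxel level, record
the largest cluster (face adjacency by default), and return the
smallest extent $k$ with empirical $P(\max \ge k) \le \alpha$
(default 10,000 iterations, mandatory seed).

Two details matter and are easy to get wrong:

* **Sidedness must match the map.** A t map is thresholded two-sidedly
  with positive and negative clusters labeled separately, so the null
  field is split the same way (each sign at rate $p/2$). An F map's
  exceedances form a single class at rate $p$, giving systematically
  larger null clusters; `mc_threshold_spec(sided = "one")` matches this
  and the pipeline uses separate extents for F and t maps. Using the
  two-sided null for an F map inflated the familywise rate from 5% to
  ~15% in calibration runs.
* **The null FWHM must model the map's true smoothness.** On the
  phantom, voxel noise is spatially independent, so calibration runs use
  FWHM = 0, where the suprathreshold process is exactly iid Bernoulli
  for any marginal distribution and the correction is exact up to the
  discreteness of the extent rule (the attained familywise level is the
  largest available tail probability $\le \alpha$, which can sit well
  below $\alpha$). For real smoothed data the FWHM parameter
  (conventionally 4 mm) carries the smoothness; note that an F field built from
  fields of correlation $\rho$ has correlation $\approx \rho^2$, so a
  z-field simulation at the map FWHM is mildly conservative-to-liberal
  depending on statistic — one reason the package also validates the
  correction end-to-end by cohort-level simulation rather than trusting
  the field model.

## Group statistics

The within-group map is a one-sample t against 1 — the normalized
global mean — so positive values mark voxels above the subject-mean
amplitude. Between groups, each voxel is fit by OLS as
`alff ~ group + age` and the group factor tested by extra sum of squares
against the age-only model, $F$ with $(g-1,\, n-g-1)$ df (vectorized
across voxels; cross-checked voxelwise against `anova(lm())` and the
$F = t^2$ identity in the two-group case). Post-hoc contrasts are
pooled-variance two-sample t maps restricted to the ANCOVA cluster mask
(Welch optional; age re-adjustment at the post-hoc stage is off by
default, matching the ambiguity of common practice). Zero-variance
voxels receive ±Inf (or 0) with a warning and are excluded from
clustering. The lesion subgroup test contrasts, within each first-level
cluster, subjects with and without a pathological lesion load — more
than one lesion per decade of age, strictly — and extracts sub-clusters
under the same voxel-p and extent rule.

## Brain–behavior stage

Scores significantly *lower* in the deficit group (unadjusted two-sample
t, direction required) are correlated with per-cluster mean ALFF across
all subjects pooled; the Benjamini–Hochberg step-up runs over the full
cluster × score family, and missing scores are handled pairwise-complete
with per-row n. The adjustment is verified against an exhaustive
definition-based oracle on every random instance up to $m = 12$.

## Numerical choices and degenerate inputs

* Ideal band-pass: inclusive band edges at the bin level; DC always
  removed; idempotent by construction.
* Amplitude convention $2|X_k|/T$: any fixed convention cancels under
  normalization (tested); Parseval bookkeeping for this scaling is
  asserted to $10^{-8}$.
* Empty significant masks, empty cluster tables and all-equal maps are
  returned as empty/zero results with warnings, not errors; impossible
  configurations (band above Nyquist, too-small grids, rank-deficient
  designs after pruning) fail fast with messages naming the offender.
* Determinism: every stochastic stage takes an explicit seed; cohort
  seeds derive from one master seed; phantom noise uses a dedicated
  Mersenne-Twister stream seeded from the subject's R stream, so
  identical inputs give bit-identical outputs.

## Problem sizes used by the test suite

Unit tests run on grids from 12×12×8 to 24×24×12 with 20–240 volumes.
The calibration studies use the default phantom (24×24×12, 238 volumes):
200 all-null cohorts of 3 × 8 subjects for the familywise check and 25
cohorts of 2 × 12 subjects for recovery of a planted 50% amplitude
increase (detected cluster vs. planted region Dice ≥ 0.5 with the
correct post-hoc sign). The acceptance script repeats these at reduced
replicate counts (60 null cohorts, 10 recovery seeds) alongside the
exact structural and oracle checks.

## Known limitations

* Spatial registration is out of scope; phantoms are generated on a
  shared grid and motion affines are consumed only for QC and
  regressors.
* The Gaussian-field Monte-Carlo null is an approximation for F maps
  and for data whose smoothness is estimated rather than known.
* Welch df for a post-hoc map is summarized at the map level (mean over
  voxels) rather than per voxel.
* The phantom's independence assumptions understate the spatial
  correlation of real group maps; calibration results transfer to real
  data only insofar as the chosen null FWHM models that correlation.
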