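---
title: "Quantifying interlesional texture heterogeneity by coefficient of variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interlesional texture heterogeneity by coefficient of variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

Patients with multifocal liver disease carry many lesions at once, and
those lesions need not look alike on CT. `lesioncv` quantifies that
*interlesional, intra-patient* heterogeneity: each lesion is reduced to a
vector of 75 second-order texture features, each patient is reduced to a
per-feature coefficient of variation (CV) across their own lesions, and
two cohorts are compared feature-by-feature with an unpaired t-test on the
patient-wise CVs. The package also ships a synthetic phantom generator
with a controllable interlesional dispersion parameter, which provides
ground truth the pipeline can be validated against.

The pipeline is

1. **I/O** — read image volumes and integer label masks (NRRD or NIfTI),
2. **lesion splitting** — one region per positive label, or 26-connected
   components of a binary mask,
3. **size filter** — drop lesions below a minimum equivalent-sphere
   diameter,
4. **feature extraction** — 75 features from five texture-matrix families,
5. **CV matrix** — one row per patient, one column per feature,
6. **screen** — per-feature two-cohort Welch t-test at `alpha = 0.05`.

# Feature extraction

## Discretization

Intensities inside a lesion are discretized with a fixed bin width
(default 25 HU) anchored at the lesion's own minimum:

```
level(x) = floor((x - min) / w) + 1,   Ng = floor((max - min) / w) + 1
```

Anchoring at the per-lesion minimum makes every feature exactly invariant
under intensity shifts of the whole lesion, which is the behaviour wanted
when the phantom generator moves lesion means around. (Implementations
that anchor bins on a global grid differ from this choice by at most a
relabeling of bin edges.)

## Matrix families

All matrices are built in 3-D on the lesion's voxel set only; voxels
outside the lesion never contribute.

* **GLCM** — co-occurrence counts over the 13 unique direction vectors at
  Chebyshev distance 1 (configurable distance). Each direction's count
  matrix is symmetrized (`C + t(C)`) and normalized; the 24 features are
  computed per direction and averaged over directions. Directions with no
  in-mask voxel pair are dropped from the average.
* **GLRLM** — maximal runs of equal level per direction, features per
  direction and averaged, as for the GLCM.
* **GLSZM** — zones of equal level under 26-connectivity (direction-free).
* **GLDM** — per-voxel dependence counts: the number of 26-neighbours in
  the mask whose level differs by at most `gldm_alpha` (default 0).
* **NGTDM** — per-level counts and summed absolute differences between a
  voxel's level and the mean level of its in-mask 26-neighbours; voxels
  with no in-mask neighbour are skipped.

The 75 features (24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM) follow
the standard reference definitions and are named
`original_<family>_<Feature>`.

## Degenerate inputs and numeric policies

Every valid region — including a single voxel and a perfectly flat
lesion — yields 75 *finite* features. The policies are:

* entropy-type features are computed as `-sum(p * log2(p))` over strictly
  positive entries, so a flat texture gives exactly 0 rather than a tiny
  negative number;
* `Correlation` and `MCC` are defined as 1 when only one grey level is
  present (a constant image is perfectly autocorrelated);
* `Imc1` is 0 when both marginal entropies vanish; the operand of the
  square root in `Imc2` is clamped at 0;
* NGTDM `Coarseness` is capped at `1e6` when its denominator vanishes,
  `Busyness` and `Strength` are 0 on a zero denominator, and `Contrast`
  is 0 when fewer than two levels are present;
* if *no* direction has a voxel pair (e.g. a single voxel), the GLCM
  falls back to the diagonal matrix of observed level frequencies.

# Lesion splitting and the size filter

Masks with labels {0, 1} are treated as binary and split into
26-connected components; any other integer labels are taken as authored
lesion identities. Lesions are filtered by equivalent-sphere diameter

```
d = (6 V / pi)^(1/3),  V = n_voxels * voxel volume (mm^3)
```

with an *inclusive* threshold (`d >= min_diameter_mm`, default 5 mm).
The equivalent-sphere rule was chosen over axis-wise calliper diameters
because it is rotation invariant and matches the volume actually used in
the descriptives.

# The CV statistic and the screen

For one patient and one feature, the CV across that patient's lesions is

```
CV = 100 * sd(x) / mean(x)      (sample sd, n - 1 denominator)
```

Patients with fewer than two lesions after filtering are dropped (with a
message). Features whose per-patient mean is not positive (possible for
signed features such as `ClusterShade`) are *flagged*, not dropped: the
raw value is kept and a parallel flag matrix marks the entry, because
silently removing them would bias the screen. An `abs_mean` variant is
available as a sensitivity option.

The screen runs one two-sided unpaired t-test per feature on the
patient-wise CVs. Welch's form is the default — cohorts of different
sizes have no reason to share a variance — with `var_equal = TRUE`
available. The primary significance flag is the raw `p < alpha` with no
multiple-testing correction, reflecting the screening character of the
analysis; Benjamini–Hochberg q-values are reported in a separate column
and never alter the primary flag. Zero-variance degenerate inputs
resolve without error (equal means: t = 0, p = 1; unequal: p = 0). The
per-patient mean CVs are the primary cohort summary; a pooled
across-all-lesions CV is offered as a secondary reading because the two
answer different questions (within-patient dispersion vs cohort-wide
dispersion).

Cohort descriptives (per-patient lesion counts, lesion volumes, optional
categorical covariates) are compared with Wilcoxon–Mann–Whitney tests,
exact when there are no ties.

# The synthetic cohort generator

Real multi-lesion CT with per-lesion annotations cannot ship with a
package, so validation rests on phantoms whose ground truth is known.
The generator's defaults are study conditions, fixed before any results
were measured.

## One lesion

A lesion is an ellipsoidal mask (nominal radius `lesion_radius_vox`,
per-axis anisotropy drawn uniformly in ±30%) filled with smoothed
Gaussian noise: white noise is convolved with a separable Gaussian kernel
(standard deviation `correlation_length_vox`, truncated at 3 sigma and
renormalized), then affinely rescaled so the in-mask sample mean and SD
*exactly* equal the requested `mean_hu` and `sd_hu`. Background voxels
sit at a liver-like 60 HU. Defaults: `mean_hu = 100`, `sd_hu = 20`,
`correlation_length_vox = 1.2`, `lesion_radius_vox = 6`, spacing
0.7 × 0.7 × 1.5 mm.

## Dispersion model

Patient-level texture parameters are drawn around the cohort prior with a
fixed 10% lognormal spread. Within a patient, each lesion's `mean_hu`,
`sd_hu` and `correlation_length_vox` are multiplied by independent
lognormal factors with `meanlog = -tau^2/2`, `sdlog = tau`, so the
factors have unit mean and CV `sqrt(exp(tau^2) - 1)`. The single knob
`tau` (`interlesional_dispersion`) therefore directly controls the
quantity the pipeline is supposed to recover: `tau = 0` makes all of a
patient's lesions statistically identical, and the parameter-level CV
grows monotonically in `tau`.

Lesion *radius* deliberately does not scale with `tau`; it carries an
independent fixed 10% lognormal jitter. This keeps texture heterogeneity
decoupled from lesion size (size is summarised separately in the
descriptives) and keeps runtime bounded at large `tau`.

Lesions are placed collision-free in an automatically sized volume: each
lesion is assigned a distinct cell of a cubic grid in random order with a
random offset inside its cell, and labels 1..k identify the lesions in
the patient's mask. All randomness derives from the
cohort seed via a per-patient seed function, so studies are byte-identical
across runs given the same spec.

## Validation scales

Two canned experiment scales are used in the tests and analysis scripts,
both chosen a priori:

* **Recovery**: 20 + 15 patients, 2–10 lesions of nominal radius 6
  (16³-voxel cells), `tau_A = 0.2` vs `tau_B = 0.4`. The screen should
  find more significant features with higher CV in cohort B, and the
  mean CV should be monotone in `tau` over {0, 0.1, 0.2, 0.4, 0.8}.
* **Null calibration**: 200 replicates of 10 + 10 patients, 2–4 lesions
  of nominal radius 3 (8³ scale), `tau = 0.3` in both cohorts, minimum
  diameter 3 mm (the default 5 mm would censor these reduced-scale
  phantoms). With 200 replicates a single feature's rejection-rate
  estimate has binomial standard error of about 0.015, so a band of
  [0.03, 0.07] cannot hold for all 75 features simultaneously even under
  perfect calibration; the asserted properties are the *pooled* rejection
  rate across non-flagged features and the *median* per-feature rate,
  both within [0.03, 0.07].

# Limitations

* Phantoms are ellipsoids with stationary Gaussian texture; they do not
  emulate real enhancement patterns, partial-volume effects at lesion
  rims, or acquisition/reconstruction variability.
* The screen tests each feature marginally; features are strongly
  correlated and no joint model is attempted.
* The CV is undefined in a meaningful sense when a feature's per-patient
  mean is near zero; flagged entries should be inspected before
  interpretation.
* No survival or outcome modelling, and no classifier of primary entity,
  is included.
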