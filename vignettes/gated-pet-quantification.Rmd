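---
title: "Gated FDG-PET quantification of right-heart function and lung metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gated FDG-PET quantification of right-heart function and lung metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petph)
```

## The measurement problem

Pulmonary hypertension (PH) drives a metabolic shift toward glycolysis in
both the pressure-overloaded right ventricle (RV) and the pulmonary
vasculature. A single ECG-gated FDG-PET/CT acquisition can in principle
quantify both phenomena at once — lung glucose uptake, RV wall uptake
relative to the LV, and RV function (volumes and ejection fraction) from
the gated frames. `petph` implements that quantification chain as tested,
deterministic code, together with a digital thorax phantom whose ground
truth is analytic, so that every formula in the chain can be validated by
exact recovery rather than by eye.

## Models and formulas

**SUV.** Activity concentration $C$ (kBq/mL) is normalized by injected
dose over body weight:
$\mathrm{SUV} = C \cdot w / D$ with $w$ in kg and $D$ in MBq, so that a
uniform whole-body distribution gives SUV 1. Body-weight normalization is
the clinical default; input volumes are assumed decay-corrected by the
scanner, and `to_suv()` applies no decay correction of its own.

**Lung SUV with tissue-fraction correction.** A lung voxel is a mixture
of air, blood and lung tissue. With the air fraction inferred from CT
density ($1 + \mathrm{HU}/1000$ is the non-air volume fraction, since air
is $-1000$ HU and soft tissue $\approx 0$ HU), three quantities are
reported per region:

* $\mathrm{SUV_M}$ — the measured mean SUV, mixture and all;
* $\mathrm{SUV_L} = \mathrm{SUV_M} / (1 + \mathrm{HU}/1000)$ — uptake of
  bulk (non-air) lung material;
* $\mathrm{SUV_T} = (\mathrm{SUV_M} - f\,\mathrm{SUV_B}) /
  (1 + \mathrm{HU}/1000 - f)$ — uptake of lung tissue proper, after also
  removing a blood compartment of volume fraction $f$ at blood-pool
  uptake $\mathrm{SUV_B}$.

The blood fraction defaults to $f = 0.16$, the literature estimate of
pulmonary blood volume; it is a parameter everywhere, never a hard-coded
constant. $\mathrm{SUV_B}$ is the pooled voxel mean over the left-atrial
cavity and descending thoracic aorta masks (a single union mean, not a
mean of two means — the source description is ambiguous and the pooled
mean weights voxels equally; the masks themselves should cover only
cavity centres). Corrections are applied to *region means*, matching how
mean HU and mean SUV are recorded per region; negative $\mathrm{SUV_T}$
(measured SUV below the expected blood signal) is returned as computed
and flagged, never clipped, because truncation would bias cohort means.

**The 24 lung regions.** Each lung is divided into upper/mid/lower
levels (equal-thickness z slabs over that lung's own extent),
anterior/posterior zones (split at the lung's own mid-coronal plane) and
medial/lateral halves (split at the lung's own mid-sagittal plane):
$2 \times 3 \times 2 \times 2 = 24$ disjoint regions whose union is the
lung mask, 12 per lung. The published protocol counts 12 regions per lung
across the three levels and two zones without stating the fourth factor;
the medial/lateral split was chosen because it is the only remaining
anatomical axis and keeps all regions comparable in size. Lower-lobe
exclusion (scatter from liver and heart) removes the 8 lower-level
regions, leaving 16.

**ED/ES extraction and RV function.** Of the eight ECG bins, frame 1
begins at the R wave; end diastole is represented by frames {1, 8} and
end systole by frames {4, 5}. These are fixed constants of the gating
convention, not inferred from the data. The two frames of a phase are
combined by their voxelwise *mean* rather than the raw sum: for
calibrated (SUV-scaled) images the mean preserves the scale while giving
the identical noise benefit; a `combine = "sum"` option remains for
count-space data. The RV cavity is segmented by seeded region growing:
the 6-connected component of voxels below `threshold_fraction` (default
0.5) of the local wall maximum, confined to a bounding box; this replaces
the manual contouring of clinical practice with a deterministic
algorithm. Volumes are voxel counts times voxel volume;
$\mathrm{EF} = 100\,(\mathrm{EDV}-\mathrm{ESV})/\mathrm{EDV}$,
$\mathrm{SV} = \mathrm{EDV}-\mathrm{ESV}$. Per-wall maximum SUV is read
on the ED image within the wall masks, and the RV/LV ratio is the ratio
of the free-wall maxima.

Segmentation failure modes mirror practice: if nothing near the seed
falls below threshold, there is no wall/cavity contrast and the study is
*non-contourable* (volumetric outputs become `NA`, wall SUVs are still
reported); if a darker cavity exists immediately next to an
above-threshold seed, the seed is misplaced and that is an error, not a
non-contourability. A region reaching the bounding box has leaked through
the wall and is likewise non-contourable.

**Echo-derived hemodynamics.** Closed forms, with units fixed at the
interface (velocities m/s, areas cm², times ms, pressures mmHg):
$\mathrm{RVSP} = 4V^2 + \mathrm{RAP}$ (simplified Bernoulli);
fractional shortening $= (\mathrm{EDA}-\mathrm{ESA})/\mathrm{EDA}\times
100\%$; Tei index $= (\mathrm{TCO} - \mathrm{ET})/\mathrm{ET}$;
$\mathrm{PVR} \approx \mathrm{TRV}/\mathrm{TVI_{RVOT}} \times 10 + 0.16$
Wood units; heart-rate recovery $=$ HR at walk end minus HR one minute
later, with negative values preserved (and flagged) because a rising
recovery heart rate is clinically meaningful. TAPSE, S′, RA volume,
strain and RV thickness are pass-through measurements.

**Statistics.** Group comparisons use the two-sample t test computed from
(mean, SD, n) summaries — exactly equivalent to the raw-data test on
moment-matched samples — with Welch as the default because the clinical
source says only "where appropriate" and Welch is safe under unequal
variances (it also reproduces the published p values for the four
summary comparisons the package re-tests). Spearman correlation uses
tie-aware average ranks with the t-approximation p value on pairwise
complete observations; exact permutation is available for small tie-free
samples. Bland–Altman agreement reports the mean difference, SD
(denominator $n-1$) and limits $\bar d \pm 1.96\,s_d$. P values carry a
journal-style display rounding (1 decimal at $p \ge 0.095$, 2 decimals
below, 2 significant digits when 2 decimals would read 0.00). No
multiple-comparison correction is applied, matching the pilot-study
convention of the source setting.

## The phantom: what it emulates and what it does not

`make_thorax()` builds a schematic beating thorax on a centred voxel
lattice (x left→right, y posterior→anterior, z inferior→superior;
0-based indices, voxel-centre coordinates):

* two ellipsoidal lungs whose voxels carry the three-compartment mixture
  (activity $= f_b\,\mathrm{SUV}_{blood} + (1-f_a-f_b)\,
  \mathrm{SUV}_{tissue}$, HU $= -1000 f_a$), defaults $f_a = 0.7$,
  $f_b = 0.16$, so lung HU is exactly $-700$;
* ellipsoidal-shell LV and RV with an interventricular septum where the
  shells overlap, a detached right atrium, a left-atrial blood pool and a
  descending aorta, all painted with configurable SUV-scale uptake
  (defaults: LV wall 2.0, RV wall 2.8, septum 2.0, RA wall 1.5, blood
  1.0, lung tissue 2.0, soft tissue 0.8 — an RV/LV truth ratio of 1.4,
  PH-like);
* an RV cavity whose volume follows the gated cycle
  $V_f = \mathrm{ESV} + (\mathrm{EDV}-\mathrm{ESV})\,\phi_f$ with
  $\phi = (1, 0.75, 0.3, 0, 0, 0.3, 0.75, 1)$, so the ED frames {1, 8}
  and ES frames {4, 5} hold exactly the true EDV and ESV (defaults 160
  and 104 mL: EF 35%, a typical PH value);
* optional i.i.d. Gaussian noise on each frame's activity (SD in SUV
  units), a proxy for reconstructed-image noise — Gaussian rather than
  Poisson-on-counts because post-reconstruction images are approximately
  Gaussian and the truth accounting stays simple.

Masks are full-grid binary volumes (the raster equivalent of drawn 3D
contours). Geometry is ellipsoids and cylinders on purpose: the claims
exercised downstream are quantitative formulas, and analytic shapes make
the ground truth exact. The phantom does *not* emulate respiratory
motion, scatter, attenuation artefacts, partial-volume blur, within-lung
heterogeneity (homogeneous lungs by default, matching the absence of
regional differences in the source setting) or realistic anatomy — so a
passing recovery test validates the formulas and their implementation,
not robustness to those physical effects on real scanners.

## The cohort generator

`make_cohort()` draws subjects through a Gaussian copula: latent normals
with Pearson correlation $2\sin(\pi\rho_s/6)$ for a target Spearman
$\rho_s$, mapped through each measure's marginal quantile function, so
rank correlations survive the monotone transforms. The default spec
mirrors a single-centre PH cohort: 8 controls, 9 idiopathic, 12
hereditary and 9 other-aetiology PH subjects. Lung SUV$_M$
(0.50 ± 0.15 PH vs 0.37 ± 0.09 control), lung SUV$_T$ (2.13 ± 0.63
idiopathic, 1.98 ± 0.81 hereditary, 1.59 ± 0.38 control) and the RV/LV
ratio (1.20 ± 0.75, 1.49 ± 1.23, 0.37 ± 0.28) follow published group
summaries for such cohorts; marginals the literature does not print
(RV volumes, EF, echo inputs, 6MWD, CAMPHOR) are clinically plausible
values for severe precapillary PH versus health, chosen once and kept.
NT-proBNP is log-normal, reflecting its heavy right tail. Echo *inputs*
are produced by inverting the closed-form formulas from drawn latent
truths (TR velocity from RVSP and RAP, ES area from ED area and
fractional shortening, and so on), which is what makes the
formula-inversion recovery test exact; rare tail draws are clamped to
keep the inversions defined (e.g. RVSP ≥ RAP). Two non-control strain
values are set missing, exercising explicit-`NA` propagation and
pairwise-complete correlation.

## Numerical choices and degenerate inputs

* Volumes are written as 64-bit-float NIfTI with a diagonal affine, so
  I/O round trips are bit-exact.
* `t_test_from_summary()` returns $p = 1$ for two identical zero-variance
  summaries and errors on unequal ones; Spearman errors on constant
  vectors rather than silently returning `NaN`.
* Segmentation is integer flood fill on a fixed connectivity; given the
  same image and seed, the mask is identical.
* Lung slab boundaries are half-voxel offsets of the lung's own z range,
  so every voxel lands in exactly one region regardless of extent
  parity.
* All randomness (phantom noise, cohort draws, missingness) flows from
  explicit integer seeds; `run_study()` derives fixed per-stage offsets
  from one root seed so partial re-runs see the same streams.

## Worked example

```{r example, eval = FALSE}
library(petph)

## a noise-free digital thorax with known truth
phantom <- make_thorax(phantom_spec(seed = 1))
quant <- quantify_subject(phantom$series, phantom$ct,
                          phantom$truth$rois, phantom$truth$rv_seed_voxel)
quant$lung      # SUV_M 0.440, SUV_L 1.467, SUV_T 2.000 over 24 regions
quant$cardiac   # EDV 160.1 mL, ESV 104.2 mL, EF 34.9%, RV/LV 1.40

## the full synthetic study: phantom QC + cohort + tables
res <- run_study(run_config(out_dir = tempfile(), seed = 11))
head(res$tables$comparisons)
```

On the noise-free phantom the recovered SUV$_T$ equals the configured
tissue uptake to machine precision (the correction is the analytic
inverse of the generator's mixing rule), the RV/LV ratio equals the
configured wall-uptake ratio, and the measured EF is within a quarter of
an EF point of truth at 2 mm voxels — pure voxelization error.

## Problem sizes used in validation

The shipped tests and the acceptance script use a 96×80×80-voxel thorax
at 2 mm spacing, heart-only grids of 150×120×150 voxels at 1 mm and
76×60×76 at 2 mm for the EF recovery sweep (true EF 20–65%, noise SD 0
and 0.05 SUV), and cohorts of 10⁴ subjects per group for the
convergence checks. These sizes were chosen so the full suite exercises
every code path at meaningful resolution while remaining quick to run on
a laptop.

## Known limitations

* The phantom's sharp compartment boundaries mean segmentation accuracy
  under realistic partial-volume blur is not measured here.
* The cavity threshold (0.5 of local wall max) is appropriate for the
  high-contrast phantom; on clinical fasting scans, where wall uptake can
  approach blood pool, the non-contourable path is the expected outcome —
  as it is in a substantial fraction of real fasting studies.
* Group marginals that the literature does not print are plausible, not
  measured; comparisons against them validate the pipeline's statistics,
  not clinical effect sizes.
* The copula reproduces pairwise rank correlations only; higher-order
  dependence is not modelled.
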