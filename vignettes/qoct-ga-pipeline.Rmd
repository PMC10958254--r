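---
title: "Quantifying geographic atrophy from OCT segmentation masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying geographic atrophy from OCT segmentation masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Geographic atrophy (GA) is the late atrophic form of non-neovascular
age-related macular degeneration: progressive loss of photoreceptors,
retinal pigment epithelium (RPE) and choriocapillaris in the macula. On
spectral-domain OCT the disease is described by three constituent features
segmented per B-scan — **RPE loss**, **photoreceptor degeneration (PRD)**
and **hypertransmission** of signal into the choroid — and by composites
derived from their per-A-scan overlap:

* **RORA** (RPE and outer retinal atrophy): A-scans where all three
  constituents co-occur. It spans incomplete (iRORA) and complete (cRORA)
  atrophy and serves as the continuous lesion measure.
* **PRD in isolation**: PRD without overlapping RPE loss or
  hypertransmission — the earliest detectable change, photoreceptor damage
  ahead of the RPE.
* **Intact macula**: the part of the 6 mm ETDRS disc free of all three
  features.

`qoctga` takes per-B-scan binary masks of the three constituents (it does
*not* segment; binarised masks and a fovea estimate are inputs), reduces
them to en-face maps, derives the composites, measures areas by ETDRS
subfield, lesion focality and perimeter, fits the longitudinal trial
endpoint model, and evaluates baseline predictors of 12-month growth.
Because the source imaging of a GA trial is not redistributable, the
package ships a synthetic-cohort simulator with known ground truth; every
stage of the pipeline is validated against it.

## Pipeline and conventions

A **segmentation volume** is a stack of `n_bscans` binary masks
(axial x lateral) for one feature of one eye at one visit, with a JSON
sidecar holding geometry (A-scan and B-scan spacing in mm, fovea position,
laterality, field extent). Volumes with fewer than 25 B-scans over the
nominal 6 x 6 mm field are flagged and excluded from analysis; when an
eye-visit has several acquisitions the one with the most B-scans is used,
ties broken by the lexicographically smallest acquisition identifier so
the choice never depends on input order.

Coordinates: en-face row 0 is the superior-most B-scan; within a B-scan,
column 0 is the temporal edge for right eyes (OD) and the nasal edge for
left eyes (OS); physical positions are mm from the superior-temporal
corner.

**En-face reduction** marks an A-scan positive if any voxel of its mask
column is positive, giving one en-face row per B-scan and one column per
A-scan. The native en-face raster is therefore anisotropic (row pitch =
B-scan spacing, typically ~0.12 mm; column pitch = A-scan spacing,
~0.01 mm). Areas of the constituents and of the pixelwise composites are
taken on this native raster — count of positive pixels times pixel area —
so the primary endpoint never passes through interpolation. Nearest-
neighbour resampling to an isotropic 0.01 mm raster happens only where
geometry requires it: ETDRS masks, lesion morphology and registration.

No interpolation is performed *between* B-scans. The per-band "any
positive voxel" reduction makes an en-face band positive when any part of
it is covered, so en-face areas carry a positive bias of roughly half the
band height times the lesion perimeter (a few percent at 49 B-scans over
6 mm). This sensitivity to B-scan density is a documented property of the
reduction, deliberately not hidden by smoothing; the simulator's ground
truth is measured on the full-resolution truth rasters and the validation
suite compares against those.

## The ETDRS grid

The grid is fovea-centred: circles of 1, 3 and 6 mm diameter split into a
central subfield, four inner-ring quadrants and four outer-ring quadrants
(superior / nasal / inferior / temporal, boundaries on the +-45 degree
diagonals). Numbering: 1 = central, 2-5 = inner superior/nasal/inferior/
temporal, 6-9 = outer likewise. Nasal direction is resolved by laterality,
so OD and OS grids mirror across the vertical meridian. Note that the
source nomenclature this package follows calls the 3 mm circle
"perifoveal" and the 6 mm circle "parafoveal", the inverse of common
usage; the package uses neutral ring names (`ring_central`, `ring_inner`,
`ring_outer`) in its outputs and leaves the labels to the caller.

Two numerical choices matter. Ring boundaries use strict inequalities
(`r < bound` goes inward) so the subfields partition the disc exactly —
per-region areas of a feature sum to its disc total to the last pixel, and
disc occupancy is identically the area-weighted mean of subfield
occupancies. Pixels exactly on a +-45 degree diagonal are assigned to the
vertical (superior/inferior) quadrants; any assignment is defensible, but
this one keeps the OD/OS mirror symmetry exact rather than approximate.
Per-cent occupancy is `100 x area(feature AND region) / area(region)`.

## Lesion morphology

Focality is the number of connected lesions in the RORA map under
**8-connectivity** — a diagonal bridge formed by a growing lesion should
join, not split, the count. Components smaller than `min_lesion_mm2`
(default 0.05 mm^2, configurable; no threshold is prescribed by the
endpoint definitions) are treated as segmentation specks: excluded from
focality and perimeter, retained in total area.

Perimeter is the length of the 0.5-level iso-contour of the mask.
Extracted from the raw binary raster, such a contour systematically
overestimates the length of a smooth boundary (about +5.5% for rendered
circles; pixel-edge counting would be worse, up to 4/pi). The package
therefore smooths the mask with a Gaussian kernel (sigma = 1.5 px) before
contouring; on rendered circles of radius 0.3-1.5 mm the error is below
0.2%, and the validation suite requires agreement with 2*pi*r within 2%.
Components too small to survive the blur fall back to the raw contour.

Longitudinal registration is translation-only, matching a workflow in
which a fovea localiser anchors the grid: each follow-up is shifted so its
recorded fovea meets the baseline fovea, then refined by maximising binary
overlap of its RORA map with baseline within +-0.25 mm. Because a grown
lesion can contain the baseline lesion entirely, the overlap objective can
plateau; exact ties are resolved toward the shift that aligns the two
lesion centroids. After alignment, every visit's recorded fovea is an
independent noisy measurement of one anatomical point, and their mean (the
consensus fovea) localises it with reduced error — the simulator-based
test verifies the RMS improvement. Rotation and scale are out of scope.

## Trial endpoints

The endpoint is change from baseline in square-root-transformed area (mm):
the square-root transform makes radial GA growth approximately linear in
time and weakens the dependence of growth on baseline size. For each
post-baseline visit the model is

```
sqrt_change ~ arm + visit + arm:visit + baseline_c + visit:baseline_c
              + (1 | eye)
```

with visit categorical, the baseline lesion area centred at its grand
mean, and a random intercept per eye; estimation is by REML (`lme4`).
LS means are model predictions per arm x visit at the grand-mean baseline;
arm contrasts versus the pooled sham arm are tested with **Wald z**
statistics. No denominator-degrees-of-freedom approximation is applied —
the package avoids implementation-specific Satterthwaite/Kenward-Roger
choices at the cost of slight anticonservatism in small samples; the
calibration study below quantifies it at the study conditions. The
"visit x baseline" term is implemented as visit-specific slopes of the
centred baseline covariate — the reading consistent with cross-level
interactions. Eyes missing a visit contribute their observed rows
(likelihood-based handling, no imputation). Baseline arm comparisons use
the two-sided Wilcoxon rank-sum test, since baseline areas are not
normally distributed. Percent reduction in growth rate is
`100 x (1 - active/sham)`, rounded to the nearest integer for reporting:
the published 12-month means 0.151 (PM), 0.202 (PEOM) and 0.277 mm (sham)
give 45% and 27%.

## Predicting growth

The predictor table holds, per eye at baseline: the PRD/RPE-loss area
ratio, isolated-PRD area and intact-macula area; the response is 12-month
growth. Two response scales are supported and never silently swapped:
square-root-area change (mm, the default, matching the endpoint scale) and
raw area change (mm^2); the choice is recorded in every report. Models are
ordinary least squares — univariable on the ratio, multivariable on all
three predictors — with two-sided coefficient p-values. "100-fold
bootstrapped" is read as 100 bootstrap resamples with replacement at the
eye level (the conventional reading; the count is configurable): each
resample is refit and its in-sample R^2 kept, reported as mean and 2.5/97.5
percentile interval, along with percentile intervals for the coefficients.
With one resample equal to the full sample the bootstrap R^2 reduces to
the in-sample R^2. Quartile stratification cuts at the sample quartiles
with values equal to a cut going to the lower quartile — deterministic and
invariant under strictly monotone transforms of the stratifying variable;
per-quartile growth is summarised with n, mean, SD and median plus a
Spearman monotonicity statistic.

## The synthetic cohort

The simulator renders what the validation needs and nothing more: binary
multifocal lesions whose square-root area is exactly affine in time.

* **Seeds**: per eye, a truncated-geometric count (mean ~3.1, max 12,
  matching the reported focality distribution) of points at least 0.3 mm
  apart near the fovea.
* **Growth**: at visit `t` months the RPE-loss region is the sublevel set
  of the Euclidean distance transform from the seed set whose pixel count
  matches `(b + g t/12)^2`, with `b` the baseline sqrt-area (gamma, mean
  7.0, SD 3.39 mm^2) and `g` the per-eye growth rate. The radius is
  solved by order statistic of the distance map — the same monotone solve
  as bisection, but it hits the target pixel count exactly, so the
  rendered areas follow the affine law to within a pixel. Lesions from
  different seeds merge naturally as they grow, so focality can decrease
  over time while area grows, as in real GA.
* **PRD** is the RPE-loss region dilated by a 0.25 mm halo — isolated PRD
  is the halo annulus, encoding photoreceptor degeneration spatially
  leading RPE loss. **Hypertransmission** keeps each RPE-loss boundary
  pixel with probability `htr_agreement` (default 0.95), interior pixels
  always: the noise stays on the boundary so the triple overlap remains
  simply connected and, at `htr_agreement = 1`, RORA equals RPE loss
  exactly — a closed-form oracle for the whole downstream pipeline.
* **Rendering**: the truth raster (default 0.01 mm/px) is sliced into
  equal-height B-scan bands; an A-scan is positive if any truth pixel of
  its band is positive, consistent with the downstream reduction. The
  default field is 6.2 x 6.2 mm: 0.1 mm of margin so that fovea jitter
  cannot push the 6 mm grid off the raster.
* **Fovea**: the true fovea sits at the field centre; the *recorded*
  fovea is jittered per visit (Gaussian, SD 0.05 mm per axis, truncated
  at +-2 SD, emulating quality-controlled localisation error).
* **Arms and rates**: sham sqrt-area growth 0.277 mm/year with arm
  multipliers 0.55 (monthly treatment) and 0.73 (every-other-month),
  i.e. the 45% and 27% growth reductions; arm sizes default to 71/61/65.
* **Variance components**: the per-eye growth rate is lognormal around the
  arm mean with CV 0.6, and measured sqrt-areas carry independent
  per-visit noise of SD 0.09 mm. These were calibrated so the SD profile
  of sqrt-area change from baseline reproduces the published sham values
  (0.15/0.21/0.26 mm at months 6/12/18): the change at visit `t` has
  variance `(0.6 x 0.277 x t/12)^2 + 2 x 0.09^2`, and the baseline
  measurement error shared by all changes of an eye contributes an
  eye-level component that the endpoint model's random intercept absorbs.
  They are calibration choices, not published facts.
* **Two paths, one latent history.** Rendered rasters follow the affine
  law *without* visit noise (so geometry oracles are exact);
  `simulate_growth_table()` adds the measurement noise analytically and
  skips rendering, which is what the statistical calibration studies use
  — 200-replicate mixed-model runs would be wasteful at raster level. The
  same root seed yields the same latent eyes on both paths, via per-eye
  sub-seeds so results do not depend on iteration order.

What the simulator does **not** emulate: lesion shape irregularity beyond
seed multifocality, OCT speckle or axial structure (B-scan masks are
binary occupancy bands), segmentation false positives away from the
lesion, inter-visit registration error of the scanner, and real
non-uniform topographic progression. Passing tests therefore demonstrate
correctness of the measurement and inference machinery under a known
growth law — not performance of any segmentation model on real OCT.

## Validation summary and problem sizes

The test suite validates, among others: byte-exact volume round trips;
composite maps against a brute-force per-pixel oracle (1,000 random
rasters) with exact partition identities; ETDRS areas within 0.5% of the
analytic circle areas at 0.01 mm/px; rendered-circle perimeter within 2%
of 2*pi*r; focality of k planted lesions equal to k; the affine growth law
on a 30-eye rendered cohort (max sqrt-area error ~1e-5 mm); LS-mean/
contrast agreement with an independent marginal-means implementation
(emmeans, asymptotic df); null calibration of the endpoint contrasts (200
cohorts of 30 eyes/arm with no treatment effect; pooled rejection ~0.06 at
alpha 0.05, within the [0.02, 0.09] acceptance band — contrasts at late
visits are individually anticonservative under the random-slope data-
generating process, which is the documented price of the random-intercept
model with Wald z) and coverage of the true month-12 treatment difference
(>= 90%, observed ~0.94 over 100 effect cohorts of 60 eyes/arm); planted-
coefficient recovery by the multivariable model's bootstrap interval
(>= 90%, observed ~0.94-0.96 with 1,000 resamples — at the default 100
resamples the percentile endpoints themselves are noisy and empirical
coverage drops a few points); permutation false-positive rates near 5%;
and quartile monotonicity on cohorts built with growth increasing in
isolated PRD. These problem sizes keep the full suite within a few
minutes on one CPU while leaving the statistical checks adequately
powered.

## Known limitations

* Areas from the en-face reduction are biased upward by the per-band
  "any" rule at low B-scan density (see above); compare like with like
  across visits acquired at equal density.
* Registration is translation-only; torsional or scale differences
  between visits are not corrected.
* The ETDRS subfield numbering (2-5 inner, 6-9 outer, superior first) is
  one convention among several in the literature; outputs carry the
  explicit region names so the mapping can be re-labelled downstream.
* Wald z contrasts are mildly anticonservative in small samples compared
  with denominator-df approximations; with ~30 eyes per arm the measured
  pooled size was ~0.06 at nominal 0.05.
* The package consumes binary masks; the choice of probability threshold
  upstream materially affects areas and is outside its scope.
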