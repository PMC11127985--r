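---
title: "Measuring liver attenuation with automatically placed parenchymal ROIs"
author: "liverroi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring liver attenuation with automatically placed parenchymal ROIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Background and model

On unenhanced CT, liver attenuation in Hounsfield units falls roughly
linearly with liver fat content, and a mean attenuation below ~40 HU is a
specific sign of moderate-to-severe hepatic steatosis. The quantity of
clinical interest is the attenuation of the *parenchyma* — the functional
liver tissue — not of the whole segmented organ: hepatic veins, bile
ducts and focal lesions are hyperattenuating relative to (fatty)
parenchyma, so a whole-organ mean is biased upward, and the bias grows
with the amount of non-parenchymal tissue included.

`liverroi` computes three estimators from a CT volume and a binary liver
mask on the same grid:

* **volumetric**: the mean over all mask voxels. Simple, but inherits the
  vessel bias described above. For a liver containing a fraction $f$ of
  vessel voxels at offset $\Delta$ HU above parenchyma, the expected bias
  is $f\Delta$ (e.g. $0.05 \times 45 = 2.25$ HU), which the test suite
  verifies on phantoms.
* **axial**: the mean over the mask pixels of the single axial slice with
  the largest cross-sectional mask area — a slice-wise variant with the
  same inclusion problem.
* **parenchymal**: emulates the manual ROI protocol (below) and is the
  method the package exists for.

A case is categorized as moderate-to-severe steatosis when its
attenuation is *strictly* below the threshold (default 40 HU); exactly
40 HU is "normal". The strictness matters only on a set of measure zero
for real data but is fixed here for reproducibility.

## The parenchymal ROI geometry

All geometry is defined on the canonical grid: axis 1 increasing toward
patient-left, axis 2 toward posterior, axis 3 toward superior
(orientation `"LPS"`), at 0.7 × 0.7 × 2.5 mm spacing. Under the
radiological display convention the minimum index along axis 1 — the
"leftmost" pixel — is the lateral margin of the right hepatic lobe, which
is the only reading under which an offset *toward patient-left* moves the
ROI center into liver parenchyma rather than out of the organ.

| parameter | default | meaning |
|---|---|---|
| `roi_area_mm2` | 200 mm² (2 cm²) | disc area; radius $\sqrt{200/\pi} \approx 7.98$ mm |
| `center_offset_mm` | 20 mm (2 cm) | distance from the leftmost mask pixel to the ROI center |
| `n_slices` | 3 | number of ROI-bearing axial slices |
| `min_axial_separation_mm` | 5 mm (0.5 cm) | minimum axial distance between selected slices |
| `clip_to_mask` | off | restrict ROI pixels to the mask |
| `min_in_mask_fraction_warn` | 0.9 | warn when a disc leaves the mask |

The procedure:

1. **Slice selection.** Axial slices are ranked by in-mask area and
   selected greedily, largest first, subject to pairwise axial separation
   of at least `min_axial_separation_mm`. When the liver is thick enough
   that the largest slices are naturally far apart, this reproduces "the
   three largest axial slices" exactly; when they cluster around the
   equator (the typical case for a smooth organ), the separation
   constraint spreads the selection by 0.5 cm steps. Equal areas are
   resolved toward the lower (more inferior) slice index, which also
   makes the symmetric-phantom selection deterministic.
2. **Center placement.** On each selected slice, the leftmost mask pixel
   column is found; among the rows attaining it, the lower median is
   taken (deterministic on even counts). The center is
   `center_offset_mm / spacing` pixels to the patient-left, rounded to
   the nearest pixel — at 0.7 mm pixels the 20 mm offset lands on 29
   pixels = 20.3 mm, i.e. within half a pixel of the nominal distance.
3. **Membership.** ROI pixels are those whose centers lie within the disc
   radius of the ROI center in physical millimetres. This
   center-in-circle rule is exact, orientation-independent, and
   oracle-checkable by exhaustive lattice enumeration (the suite does
   exactly that); at default spacing the disc holds 405 pixels =
   198.45 mm², within 1% of the nominal 2 cm².

The per-ROI means are averaged *unweighted* rather than pooled by pixel:
disc pixel counts are nearly identical across slices, and unweighted
averaging mirrors how independent reader ROIs are combined. Discs are not
clipped to the mask by default — a manually drawn circular ROI averages
everything inside the circle, and the 2 cm offset is designed to leave
~1 cm between disc rim and liver contour, so the disc is expected to be
fully interior. For over-segmented masks the `clip_to_mask` flag and the
in-mask-fraction warning (< 0.9) cover the edge cases. A disc that would
leave the image grid is an error naming the slice; if fewer than
`n_slices` slices can be selected, the feasible ROIs are returned with a
warning.

The 0.5 cm figure is read as the spacing *between the selected slices*
(not as an offset from the single largest slice); both are expressible
through the parameters, and the default reproduces a symmetric ellipsoid
selection of equator and equator ± 2 slices.

## Volume handling

* NIfTI-1 is read and written via `RNifti`; spacing and orientation come
  from the affine and are reported as found — nothing is silently
  reordered. Header floats are stored in single precision, so spacings
  are snapped to 7 significant digits on read.
* `canonicalize()` permutes and flips axes to `"LPS"`; it is idempotent
  and preserves the voxel multiset.
* `resample()` uses trilinear interpolation for CT and nearest-neighbor
  for masks, with grids aligned at the first-voxel center and no
  extrapolation (the output extent never exceeds the input extent; it is
  preserved to within one voxel per axis). Whether reference tools
  resample label images with nearest-neighbor or linear-then-threshold is
  generally undocumented; nearest-neighbor is chosen here and is a known
  source of sub-voxel disagreement near mask boundaries.
* `largest_component()` uses 26-connectivity (the common default for
  organ masks, robust to thin anisotropic bridges); size ties go to the
  component containing the smallest raster index, making results
  platform-independent.
* Voxels are point samples at their centers; every physical distance in
  the package is a distance between voxel centers. Indices are 1-based
  (R convention).

## Segmentation metrics

Overlap: Dice `2|P∩R|/(|P|+|R|)` and Jaccard `|P∩R|/|P∪R|`. Surfaces are
mask voxels with at least one non-mask 6-neighbor (volume borders count
as outside); distances are Euclidean between surface-voxel centers in
mm, honoring anisotropic spacing — the conventions of the standard
medical-segmentation metric packages. The Hausdorff distance is the
exact maximum over both directed maxima (no 95th-percentile variant);
the ASSD is the pooled mean of all directed nearest-surface distances
from both surfaces (i.e. surface-size weighted). Nearest-neighbor
searches run in compiled code and are validated in the suite against an
exhaustive O(|S₁||S₂|) pure-R oracle on random masks up to 20³ voxels.

## Agreement statistics

* **KS**: two-sided two-sample test with the asymptotic Kolmogorov
  p-value (`stats::ks.test`, `exact = FALSE`), applied to the two value
  distributions (method vs. reference). Under the null the suite checks
  the empirical type-I error at α = 0.05 over 200 replicates.
* **Bland–Altman**: differences `method − reference`; limits of
  agreement `mean ± 1.96 · SD` with the sample (n−1) SD.
* **ICC(2,1)**: two-way random effects, absolute agreement, single
  measures, from the ANOVA mean squares; 95% CI by the McGraw–Wong
  F-distribution method. Cross-checked against an `aov()`-based
  variance-components oracle and frozen reference values from an
  independent implementation. A constant matrix has no defined ICC and
  errors; numerically identical raters return ICC 1 with a degenerate
  interval.
* **MAE and MSE** are both reported under unambiguous names (published
  tables sometimes conflate the two labels).
* **Classification**: positive iff attenuation < threshold; AUC of the
  negated score by the rank (Mann–Whitney) formulation with average-rank
  tie correction, equal by construction to the all-pairs concordance
  count (verified exhaustively in the suite). CIs are percentile
  bootstrap (case resampling, seeded, default 1000 replicates, 2.5/97.5
  percentiles); BCa was not used — the percentile flavor is the simplest
  method consistent with plain "bootstrap sampling", and single-class
  replicates are dropped with their count reported.

## The phantom: what it emulates, and what it does not

`generate_phantom()` builds an ellipsoidal liver (default semi-axes
60 × 45 × 42 mm on a 192 × 160 × 40 grid at 0.7 × 0.7 × 2.5 mm) filled
with Gaussian parenchyma (default mean 56.33 HU — a typical
non-steatotic cohort mean — and SD 10 HU, a realistic unenhanced-CT
noise level), plus straight cylindrical vessel tubes (radius 3 mm,
default 5% of liver voxels, +45 HU) along random interior chords, on a
uniform 20 HU soft-tissue background. Straight cylinders are the
simplest structure reproducing the vessel-shaped heterogeneity the
manual protocol avoids; the +45 HU offset is a fixture choice (portal
blood is markedly hyperattenuating relative to fatty parenchyma), not a
measured value. The final tube is trimmed along its chord so the
realized vessel fraction equals the target to within one voxel, which
makes the analytic mixture mean $\,(1-f)\mu + f(\mu+\Delta)$ exact and
lets the suite verify the volumetric bias sharply.

With `vessel_placement = "central"`, vessels are excluded from liver
within `central_margin_mm` of the leftmost margin along the
patient-left axis. The ROI disc reaches `center_offset_mm + radius`
≈ 28 mm from the leftmost pixel, so the exclusion must be at least that
for ROIs to be vessel-free by construction; the default margin is 30 mm
(28 mm plus a 2 mm guard). With a smaller margin the vessel-free
property degrades from a guarantee to a probability, which the
noise-free exactness tests rely on.

What the phantom does **not** emulate: ribs, lungs and air (no other
organs at all), partial-volume blur at the liver boundary,
beam-hardening or scanner-dependent noise texture, contrast enhancement,
irregular liver shape, or segmentation errors correlated with steatosis.
Passing phantom tests therefore demonstrates the *geometric and
statistical correctness of the measurement machinery* — placement rules,
estimator definitions, bias mechanics — not clinical performance on
real CT, which depends on segmentation quality and anatomy the phantom
deliberately omits.

`perturb_mask()` supplies controlled mask degradations (6-connected
dilation/erosion, rigid shift, spurious disconnected blob) for metric
and postprocessing tests.

## Problem sizes used in validation

The suite validates estimator bias and unbiasedness on 50-seed phantom
ensembles at a 128 × 112 × 30 grid (semi-axes 40 × 32 × 30 mm), a size
chosen so the full ensemble runs in seconds while leaving Monte-Carlo
standard errors an order of magnitude below the effects being measured
(vessel bias 2.25 HU vs. ROI-noise SE ≈ 0.3 HU per phantom). Geometry
checks run on the full-size default phantom. Oracle-equivalence checks
for metrics use random masks up to 20³ voxels, where exhaustive pairwise
oracles are exact and fast.

## Known limitations

* The liver must be fully inside the grid for the phantom, and the ROI
  procedure assumes the segmentation contains the lateral right-lobe
  margin; chest CTs that truncate the liver inferiorly will select
  whatever slices the mask offers and warn when fewer than three are
  feasible.
* Nearest-neighbor mask resampling can shift boundaries by up to half a
  voxel; volume is conserved only to a few percent for smooth shapes.
* The axial-separation reading of the slice-selection rule is a
  documented choice among two plausible interpretations (see above).
* ICC confidence intervals assume the two-way random-effects normal
  model; they are not distribution-free.
* The package measures attenuation given a mask; it does not segment.
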