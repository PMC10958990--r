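---
title: "Simulated DXA projections and the size-adjustment mechanism: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated DXA projections and the size-adjustment mechanism: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudoDXA)
```

## The scientific problem

Areal bone mineral density (aBMD), the quantity a clinical DXA scan reports
for the femoral neck (FN), is bone mineral content (BMC) divided by the
projected bone area. Low aBMD predicts low whole-bone strength, but the
association differs by sex: at the same aBMD, male proximal femurs are
roughly a thousand newtons stronger than female ones. `pseudoDXA`
implements, as a fully synthetic and therefore fully testable pipeline, the
analysis strategy that exposes *why*: the discrepancy is created by the act
of dividing BMC by a bone-size measure, because male and female femoral
necks differ in three structural ways that affect the numerator and the
denominator of aBMD differently:

1. more bone mass per unit volume in men,
2. more circular cross-sections in men, placing more mass out of the DXA
   image plane (captured by BMC and by the second moment of area about the
   superior-inferior axis, I~SI~, but not by projected area), and
3. different cortical/trabecular proportions at a given BMC.

The package provides (i) a calibrated generator of voxelized FN phantoms
with known sex-specific structure, (ii) the image-processing chain
(Hounsfield calibration, anteversion rotation, VOI extraction,
segmentation, cortical/trabecular partition), (iii) pseudoDXA projection
and 3D morphometry, and (iv) the statistical machinery (age adjustment,
ANCOVA slope/elevation comparison at the pooled-range midpoint,
percent-of-mean differences, multivariable models with VIF screening,
ICC reliability).

## The phantom model

Every measured quantity is defined on a 15-mm FN volume of interest, so
the generator idealizes the neck as a straight elliptical-annulus tube:

* outer ellipse with superior-inferior (SI) diameter equal to the FN width
  (FNW) and anterior-posterior (AP) diameter `ap_si_ratio * FNW`
  (`ap_si_ratio` is the cross-sectional circularity; 1 = circular);
* a cortical shell of uniform thickness *t*, modelled as the region between
  the outer ellipse and an inner ellipse with both semi-axes reduced by *t*
  (true offset curves of an ellipse are not ellipses; the reduced-semi-axes
  inner boundary is the standard idealization, and it is the one under
  which the idealized-geometry percent-gain triple below is mutually
  consistent);
* a trabecular interior realized either as a Bernoulli random field at the
  target BV/TV smoothed by one morphological closing (connected,
  stochastic), or as a regular rod lattice (deterministic, used for
  partition phantoms). In both cases random voxel flips adjust the realized
  interior fill to the BV/TV target exactly.

A prismatic tube exercises the identical code paths as a curved neck for
every parameter the analysis uses, and admits closed forms:
for outer semi-axes *a* (SI), *b* (AP) and thickness *t* (cm),

* Ct.Ar = pi (ab - a'b'), with a' = a - t, b' = b - t,
* I~AP~ = (pi/4)(b a^3 - b' a'^3) (distances SI),
* I~SI~ = (pi/4)(a b^3 - a' b'^3) (distances AP),

against which the voxel morphometry is verified to better than 1 percent
at 50-micron voxels, with the error shrinking roughly linearly in voxel
size. These closed forms also power the `generate_cohort(mode =
"analytic")` fast path, used for large repeated-seed statistical
experiments; the voxel and analytic paths are tested to agree within 5
percent on matched donors.

One consequence of the prismatic idealization worth knowing: the bone
silhouette is exactly FNW x VOI length, so aBMD and BMC/FNW are exactly
proportional and their regressions coincide. On real (or curved/tapered
synthetic) anatomy they differ slightly.

## Generator calibration

All continuous parameters are truncated normals whose *truncated* mean
equals the requested mean (the location is solved numerically); with plain
truncation the asymmetric age bounds would bias the female mean age by
almost two years. Per-sex defaults (means +/- SD, truncation bounds in
brackets) and their provenance:

| parameter | female | male | source |
|---|---|---|---|
| age (y) | 67.8 +/- 19.0 [24, 97] | 59.8 +/- 19.1 [18, 89] | published descriptives |
| FNW (mm) | 31.33 +/- 1.73 | 36.20 +/- 2.47 | area / 1.5 cm (area 4.70 / 5.43 cm2) |
| circularity | 0.88 +/- 0.05 | 0.95 +/- 0.05 | chosen: direction of the shape finding |
| cortical thickness (mm) | 1.183 +/- 0.35 | 1.282 +/- 0.30 | solved from cortical BMC 80.1 / 104.4 Mvox |
| BV/TV | 0.130 +/- 0.030 | 0.146 +/- 0.048 | solved from trabecular BMC 56.6 / 93.8 Mvox |
| PYD (mm) | 2.0 +/- 0.9 | 2.5 +/- 1.1 | chosen: realistic post-yield deflection scale |

BMC-type outputs are reported in units of 10^6 *reference voxels* (27 um
edge, the nano-CT acquisition scale the descriptive tables are printed
in); cohorts simulated at any working voxel size are converted by
`(voxel / 0.027)^3`. The geometry means for thickness and BV/TV are the
exact closed-form solutions of the annulus equations given the published
compartment masses, FNW and circularity; the SDs were chosen so the
propagated compartment-BMC SDs match the published ones. Age slopes
(+0.02 mm/y FNW, -0.004 mm/y thickness, -0.0006/y BV/TV) are small,
realistic aging trends whose only analytic role is to make the
age-adjustment stage meaningful; they are removed by it.

The strength model is linear in structure,

    strength = 1431 + 21.8 Ct + 29.3 Tb - 281 Area - 6 Age + 66 Sex + e,

with Ct/Tb in 10^6 reference voxels, e ~ N(0, 800^2) N, strength floored
at 50 N (with a warning) in the rare deep-left-tail draw. The slopes are
the published compartment-level multivariable coefficients; the intercept
reproduces the female mean strength (3108 N). Two deliberate choices:

* **Residual sex offset 66 N, not the published 606 N.** The compartment
  model's sex term was not significant in the source analysis, and the
  package's headline experiment requires a generator in which strength
  given BMC is sex-neutral (the null result for the raw-BMC regression).
  Because the area coefficient is negative and the sexes differ in
  cortical/trabecular mix, a zero sex offset actually leaves a small
  *negative* conditional-on-BMC offset (about -66 N, measured by the
  elevation-difference estimator over repeated cohorts and matching the
  analytic expectation); the 66 N default cancels it. The sex difference
  in strength thus emerges from structure alone.
* **PYD is sampled, not derived, and carries a zero default coefficient.**
  Post-yield deflection enters the fourth multivariable model as a
  covariate; its mechanical derivation belongs to the validation study of
  the pseudoDXA method, outside this package's scope.

With these defaults the simulated cohorts reproduce the direction of every
published sex difference (male > female for strength, area, BMC, aBMD;
female > male for percent cortical), within-sex strength-aBMD R^2 of
~0.45, and the headline contrast: a significant elevation difference for
strength vs aBMD and vs every size-adjusted BMC, but not for strength vs
raw BMC.

## Image-processing stages

**HU calibration** is a two-point affine map (air to -1000 HU, water to
0 HU); the hydroxyapatite phantom reading is converted and reported for
drift monitoring only, since the mapping itself is fully determined by the
two anchors.

**Rotation** (anteversion, default 15 degrees in the real-data protocol)
is a rigid rotation about a grid axis through the volume center, inverse-
mapped with nearest-neighbor resampling for labels and bilinear for
intensities, output grid enlarged to the rotated bounding box. Multiples
of 90 degrees are lattice-exact. Synthetic phantoms are generated already
aligned, so the cohort pipeline does not rotate by default.

**VOI extraction** takes `round(width / spacing)` consecutive slices
(round half up - 15 mm at 27 um is 556 slices), centered at the volume
midpoint for prismatic phantoms or at an explicit neck-axis coordinate for
real data. Repeated extraction is bit-identical; with sub-voxel center
jitter the test-retest ICC(2,1) of area and BMC exceeds 0.99, mirroring
the reliability experiment of the source protocol.

**Segmentation** replaces the original learning-based approach (whose
trained networks are another study's contribution) with deterministic
operations: bone-from-background by strict-inequality thresholding (fixed
or Otsu; threshold logged), and cortical-from-trabecular by morphology.
The partition closes the bone mask (sealing shell pores), hole-fills it to
get the periosteal region, then closes the *interior pore space*; because
solid cortex contains no pores, the closed pore space stops at the
endosteal surface, and its hole-filled largest connected component is the
endosteal region. Bone inside it is trabecular, the rest cortical - an
exhaustive, exclusive partition. The default closing radius is 0.3 mm:
large enough to bridge trabecular pores at the default voxel size, small
enough not to erode the compartment boundary (a closing at the
cortical-thickness scale would solidify the entire stochastic interior
and leave no cavity at all). On shell-plus-rods phantoms at BV/TV 0.3 the
cortical label agrees with the generator's at Dice >= 0.95, and a full
segment-then-partition pass agrees with generator labels on every
downstream parameter within 5 percent at 100 HU noise. No manual
correction step exists; phantom pipelines may bypass segmentation and use
generator labels directly (the two routes are tested to agree).

## Projection and measurement conventions

The pseudoDXA image counts bone voxels of a compartment along the AP ray
per (neck-axis, SI) pixel; the image sum equals the compartment voxel
count exactly, every run. "Area" is the *bone silhouette* area (pixels
with any bone), not the enclosing rectangle: the published areas
(4.7-5.4 cm2 for a 1.5-cm-wide ROI) imply ~3.1-3.6 cm mean widths, which
only the silhouette definition reproduces. Whether a minimum projected
thickness should instead define the silhouette is unstated in the source;
any-bone was chosen and is flagged here. aBMD = BMC / area holds to
machine precision by construction. FN widths are per-column SI extents of
the silhouette (mean and minimum). Section properties are computed per
slice - Tt.Ar from the hole-filled silhouette, moments about the
centroidal axes of the filled silhouette, summed over bone voxels - and
averaged across slices (the source phrasing reports slice-averaged areas;
whether moments were slice-averaged or mid-slice is unstated, and the
slice average was chosen for consistency). BV/TV divides trabecular
voxels by the endosteal (interior) volume. Size-adjusted BMC variants are
BMC/FNW, BMC/area^1.5 and BMC/Tt.Ar; on prismatic phantoms Tt.Ar- and
Tt.Vol-adjusted BMC correlate above 0.99, which is why only the former is
carried through the report tables.

## Statistical conventions

* **Percent differences** use the percent-of-mean convention,
  100 (M - F) / ((M + F)/2). This is not cosmetic: it is the only
  convention under which the published elevation tables and the
  idealized-geometry percent triple are internally consistent, and
  `shape_gain_predict()` relies on it.
* **Age adjustment** fits value ~ age *within each sex* and moves every
  donor to 65 years along the group's line. Pooled adjustment (available
  via `by_group = NULL`) would transfer the 8-year sex age-gap into every
  adjusted variable. The source does not state its grouping; this choice
  is logged in the returned attribute.
* **ANCOVA** tests slope equality by the interaction F-test and elevation
  by the group term in the common-slope model; elevations are intercepts
  of per-group fits after shifting x by the pooled-range midpoint
  (min + max)/2, with standard OLS intercept CIs (the source's CI method
  is unstated). Midpoint shifting provably changes intercepts only. The
  elevation-difference CI is read from the common-slope model's group
  coefficient.
* **t-tests** are pooled-variance by default (Welch by flag);
  no multiple-testing correction is applied, alpha = 0.05 per test,
  matching the source analysis.
* **Normality** uses the D'Agostino-Pearson omnibus K^2 (skewness and
  kurtosis Z transforms), implemented here because no installed R package
  provides it, and verified against an independent implementation on
  frozen data.
* **VIF screening** computes VIF_j = 1/(1 - R^2_j) and iteratively removes
  the worst term above 10; perfect collinearity yields infinite VIF and is
  resolved by the same loop.
* **ICC** is ICC(2,1) - two-way random effects, absolute agreement, single
  measure - with the Shrout-Fleiss F-based CI, the standard form for
  test-retest reliability; the source names no form.

## Calibration experiments and their problem sizes

The package ships its own statistical audit, used by both the test suite
and `scripts/acceptance.R`:

* `ancova_null_calibration()`: 1000 null replicates at n = 50/group; the
  elevation test rejects at 3-7 percent.
* `elevation_recovery()`: 500 replicates with a 1045 N offset injected on
  aBMD-scale x at 800 N residual noise; mean recovered offset within ~1
  percent and 95 percent CI coverage within [0.92, 0.98]. (Both bounds
  have Monte-Carlo error of order 1 percent at 500 replicates.)
* `coefficient_recovery()`: 500 cohorts at the study sample size (51 + 44)
  recover the cortical and trabecular slopes with mean bias well under 5
  percent.
* `mechanism_replication()`: 20 cohorts of 200/sex; the fraction of seeds
  reproducing the headline contrast is ~0.9-1.0.
* The voxel-mode calibration cohort in the acceptance script uses 200
  donors/sex at 0.25-mm voxels - the size at which voxelization bias in
  the silhouette (under half a voxel on a ~31-mm width) is comfortably
  below the sampling SE of the mean.

## What passing tests do and do not show

The generator emulates the *statistical structure* the analysis assumes -
sex-specific size, shape and compartment distributions, a structure-driven
strength model, age trends, missing-strength rates (2/51 female, 4/44
male) - not real bone. It has no curved neck or trochanter, no trabecular
anisotropy or microarchitecture, no X-ray physics (scatter, beam
hardening, detector response), and the cohort-level published results it
is calibrated against came from 95 real cadaver femurs, so agreement here
validates the *pipeline and the mechanism*, not any claim about donors.
Numerical edges worth knowing: thresholding ties go to background;
slices without bone are excluded from section properties with a warning;
an empty pseudoDXA image has undefined aBMD and errors; the idealized-geometry
fit refuses geometrically infeasible percent triples; voxel sizes coarser
than half the cortical thickness are rejected rather than silently
under-resolving the shell.
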