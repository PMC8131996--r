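---
title: "Quantifying nonexudative MNV on SS-OCTA: models, parameters, and validation"
author: "octamnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nonexudative MNV on SS-OCTA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octamnv)
```

# The problem

Type 1 macular neovascularization (MNV) can sit quietly under the retinal
pigment epithelium (RPE) for years before leaking. Swept-source OCT
angiography (SS-OCTA) resolves these nonexudative lesions and their
surroundings well enough to ask which imaging biomarkers, measured at two
visits before exudation, differ between eyes that go on to leak and eyes
that stay dry. `octamnv` implements that full measurement pipeline —
lesion area, choriocapillaris (CC) flow deficits in concentric rings
around the lesion, intralesional vessel area/skeleton density (VAD/VSD),
pigment-epithelial-detachment (PED) volumetry, mean choroidal thickness
(MCT) and choroidal vascularity index (CVI) — together with the
two-group statistics layer (pooled-t and bootstrap confidence intervals
with Shapiro-Wilk gating, Fisher's exact test).

Because no raw study volumes are publicly deposited, the package ships
seeded phantom generators that emulate every input with analytic or
brute-force-counted ground truth. Every measurement stage is validated by
parameter recovery on those phantoms, and the statistics layer by exact
reproduction of the published summary-statistics intervals.

# Coordinate and unit conventions

* x is the fast axis (A-scans within a B-scan), y the B-scan index, z depth
  increasing posteriorly; all rasters are `(ny, nx)` matrices indexed
  `[y, x]`, volumes `(nz, ny, nx)` arrays.
* Surfaces store micrometres from the anterior face of voxel plane 1;
  plane *k* spans `[(k-1) pitchZ, k pitchZ)`. Pixel `(y, x)` has its
  center at `((x-0.5) pitchX, (y-0.5) pitchY)` um.
* Depths, pitches and thicknesses are um; areas mm^2; volumes mm^3.
  Conversion happens only when metrics are emitted, so slab arithmetic
  never mixes units.

# En face slabs and conditioning

Two slabs drive the en face analysis. The ORCC slab runs from the outer
retinal boundary to the innermost CC, which we resolve as Bruch's membrane
(BM) + 4 um so that it abuts the CC slab — a 16-um slab whose anterior
boundary sits 4 um beneath BM — with no gap. `extractEnface()` treats each
A-scan as piecewise constant over voxel planes and integrates exactly over
`[top, bottom)`, so sub-voxel boundary offsets receive fractional weight;
with BM at 300 um and 4-um axial pitch the CC slab averages exactly planes
77–80. Mean projection is the default for both flow and structure: for
thin slabs it is robust and linear, and the projection choice is not
otherwise constrained.

Retinal-vessel projection artifacts are removed by mask-and-inpaint:
masked pixels are filled from the ring of unmasked neighbours and then
relaxed to the discrete Laplace interpolant (Jacobi iterations to a 1e-9
relative tolerance). The operation leaves unmasked pixels untouched and is
idempotent. The original artifact-removal algorithm is not described in
enough detail to re-implement verbatim; mask-and-inpaint is a documented,
testable stand-in with the same contract.

CC flow is compensated for signal loss under overlying anatomy by
dividing by a smoothed, floored version of the structural slab:
`out = flow * mean(S) / S_smoothed`, rescaled to preserve mean flow. The
smoothing sigma (default 3 px) exists for real images, where the structure
image carries speckle of its own; on a synthetic knife-edge shading field
the exact division (`sigmaPx = 0`) flattens the shading to machine
precision, and with the default smoothing flatness holds outside the edge
transition band. The formula is one published reading of structural
compensation; it sits behind a single interface so an alternative can be
swapped in.

# MNV segmentation and lesion metrics

The study used a validated proprietary algorithm for ORCC flow detection;
its operators are unpublished. `segmentMNV()` is a transparent substitute:
background statistics are estimated outside a 600-um buffer around a
provisional Otsu lesion, the image is thresholded at background mean +
k SD (k = 2), closed with a 2-px disc, hole-filled, and components below
0.01 mm^2 dropped. It is validated only on phantoms (Dice >= 0.95
noise-free; area error < 5% at a contrast-to-noise ratio of 5, defined on
the weakest contrast in the image, lesion background vs. scan background).
A precomputed mask can always be supplied instead.

Area is pixel count times pixel area; the square-root transform
stabilizes test-retest variance across lesion sizes. The greatest linear
dimension (GLD) is the maximal pairwise distance between boundary pixel
centers (computed on the convex hull). Eligibility mirrors the study's
exclusions: GLD < 250 um, area < 0.2 mm^2, or a lesion touching the scan
border. Foci: 8-connected components are merged when their boundaries
come within 600 um — two lesions are discrete only when their 300-um rims
do not overlap. Months are 365.25/12 = 30.44 days throughout; the study
never defines "per month", and this choice reproduces its figure-caption
rates (e.g. 5.77 to 5.74 mm^2 over 84 days = -0.0109 mm^2/mo).

# CC flow deficits

Rings are built from an exact Euclidean distance transform of the MNV
mask (a two-pass separable lower-envelope algorithm that honours
anisotropic pixel pitch): R1 = 0–300 um from the margin (one degree of
visual angle), R2 = 300–600 um, R3 = the rest of the scan excluding the
lesion. Membership is by pixel center; the partition property
`|MNV|+|R1|+|R2|+|R3| = nx*ny` is asserted in tests.

Flow deficits are pixels below a global threshold. Two strategies exist
because the referenced normative threshold value is not printed in the
study: `mean_sd` computes mean - k SD (k = 1) over the analyzed area
excluding the MNV, per image; `fixed` applies an absolute (normative)
threshold. Components with equivalent diameter `2 sqrt(A/pi)` below 24 um
(area < 452.39 um^2) are removed as speckle — at 12-um pitch that removes
<= 3-pixel components (432 um^2) and keeps >= 4 pixels (576 um^2,
d = 27.1 um). FD% is deficit pixels over region pixels; the mean
individual FD area is computed over components clipped to each ring (a
straddling deficit contributes its clipped parts to each ring), keeping
numerators and denominators consistent per region.

Phantom recovery uses the `fixed` strategy at the phantom's design
midpoint: the per-image `mean_sd` rule is intentionally adaptive, and
under heavy pixel-scale speckle it marks the low tail of the background
(~1–2 percentage points of surviving false positives at a
contrast-to-noise ratio of 5), which is exactly the regime a normative
threshold is for — the phantom's intensity scale is known by
construction, as a normative database's is. With the fixed threshold the
recovered regional FD% matches construction truth to well under 0.1
percentage points at that noise level.

# VAD and VSD

Vessel extraction inside the lesion follows the "Hessian filter plus
adaptive thresholding" recipe with the unpublished constants made
explicit and configurable: a multiscale Frangi-style tubularity response
(scales 1–3 px, bright vessels), thresholded at 25% of its maximum,
united with a local-mean adaptive threshold (33-px window; the offset
default is negative, i.e. the threshold sits 10% of the dynamic range
*above* the local mean, so flat avascular regions are rejected — a
union of the two detectors captures thin vessels and large trunks).
Components under 3 px are despeckled. Skeletonization is Guo–Hall
two-subiteration thinning, chosen over Zhang–Suen because it preserves
endpoints (a 3 x 100 px bar thins to 98 px, matching independent
implementations of the same algorithm). VAD and VSD are unitless pixel
ratios with the lesion pixel count as denominator.

Skeleton pixel counts are used for VSD (not Euclidean arc length with
diagonal sqrt(2) steps) because the published definition is a pixel
ratio. Two consequences are documented rather than hidden: thinning
under-measures true centerline length by the endpoint/junction
correction (a few percent for lesion-scale branches), and VSD is only
approximately invariant under 90-degree rotation (directional bias of
the subiterations, ~2–3%).

# PED volumetry

Elevation = `max(0, bm_z - rpe_z)`: the RPE anterior to BM encodes the
detachment. Area counts pixels above a configurable elevation floor
(default 0, since the manufacturer algorithm's floor is unprinted) and
volume integrates height over those pixels; conversions are exact. MNV-PED
metrics restrict the height map to the lesion footprint, excluding drusen.
The Gaussian-bump phantom has closed-form volume `2 pi sigma^2 h`
(0.0393 mm^3 for h = 100 um, sigma = 250 um), cross-checked against
fine-grid numeric integration in the tests; the pipeline recovers it to
well under 2% at 12-um pitch, and grid refinement by 2x moves the
estimate by < 0.5%.

# Choroid: MCT and CVI

Attenuation compensation divides each voxel by (twice) the remaining
integrated signal beneath it, `I^n / (2 sum_{z'>z} I^n dz + eps)` with
n = 1 and a relative floor eps = 1e-6 of the maximal tail. This inverts a
single-scatter Beer–Lambert model in which backscatter is proportional to
the attenuation coefficient; it removes shadows cast by overlying layers
and is invariant to global intensity scaling. The output is rescaled
offset-free (maximum matched to the input maximum) so intensity ratios
survive. The reference method's exact constants are unpublished; n and
eps are config keys.

Thickness is CSI minus BM per A-scan; MCT averages it over pixel centers
within a fovea-centered 5-mm circle (no partial-pixel weighting; <= 0.2%
area error at 12-um pitch; the circle must fit inside the scan, hence the
12 x 12-mm pattern). Choroidal vessels appear dark, so slab intensities
are inverted and a single Otsu threshold is computed from the histogram
of all slab voxels (global, matching the stated method; a per-B-scan mode
exists for sensitivity analysis). Whether the study thresholded
compensated or raw intensities is implied but not stated; compensated is
the default here, raw is exposed.

# Phantoms: what they emulate, and what they do not

* **Lesion/vessel phantom.** A disk lesion with radial branching vessels:
  spokes with mean-reverting direction (4-px steps, 0.15 rad direction
  noise) so that curvature stays resolved at the 12-um pixel scale —
  sub-resolution wiggle would make "centerline length" ill-defined — and
  branches do not co-run, so the union of width-1 rasterized centerlines
  *is* the skeleton-length ground truth of the width-3 map. Wide strokes
  get extended caps (half a width beyond each end) so the tube's medial
  axis spans the full centerline. VSD recovery is validated to within 10%
  of that truth on 20 trees at a 900-um lesion radius, the cohort's
  typical lesion scale.
* **CC phantom.** Background flow with rasterized deficit disks, optional
  multiplicative speckle and a shading field shared with the structural
  image (so compensation tests have a known inverse). Speckle is
  pixel-iid Gaussian: the study names speckle only as the cause of
  sub-24-um false deficits, and any small-grain noise exercises that
  filter; real OCTA speckle is spatially correlated and
  signal-dependent, which these phantoms do not model.
* **PED phantom.** Gaussian bumps on a flat BM; closed-form volumes.
* **Choroid phantom.** A bright-stroma slab with dark vessels (whole
  planes for an exact fraction, or random cylinders counted voxel-wise),
  behind a Beer–Lambert forward model (mu proportional to reflectivity,
  absorbing sclera) so that attenuation compensation inverts exactly the
  physics the phantom puts in. Passing these tests shows the
  compensation/Otsu/counting chain is correct, not that the single-scatter
  model captures real choroidal optics.
* **Cohort generator.** Draws visit-2 values and monthly rates per metric
  from the published group moments (normal or right-skewed shifted
  lognormal), inter-visit intervals of 3.6 +/- 2.1 months (dry) and
  2.7 +/- 1.7 months (exudating), and back-computes visit 1. It emulates
  the summary table's moments, not the joint correlation structure of
  real eyes.

# Statistics layer

Group summaries are mean/SD/median/IQR per visit, difference, and monthly
rate. Between-group 95% CIs (dry minus exudating, matching the published
sign convention) use the equal-variance pooled Student's t — chosen over
Welch because it reproduces the published intervals exactly from the
printed group SDs with df = 19 — with a percentile bootstrap
(B = 2000, seeded) selected per metric when Shapiro–Wilk rejects
normality in either group at alpha = 0.05 (per-group gating is the
default; pooled-residual gating is available, as the study does not say
which was used). The published intervals flagged as bootstrap-derived
cannot be reproduced from summary statistics — the resamples need the raw
per-eye values — so they are validated instead by calibration: the
percentile interval tracks the pooled-t interval within 10% on large
normal samples and attains 95% +/- 2% coverage over 500 seeded
replications. One published mean difference (VSD at visit 2, 0.037) was
computed by the authors from unrounded per-eye values and differs from
the difference of the rounded printed means (0.040); the printed CI
bounds reproduce only around the printed difference, which the tests
therefore use as the interval center.

`fisherExact2x2()` delegates to the standard two-sided conditional test
and is checked exactly against brute-force hypergeometric enumeration for
all tables with total up to 16 and sampled tables up to 30; the
published multifocality table (6/18 monofocal vs 3/3 multifocal eyes
exudating) gives p = 0.063.

# Visit-pair selection

Exudating eyes contribute the last two visits strictly before the
exudation date (operationally, the first anti-VEGF injection). Dry eyes
contribute the *latest* consecutive pair whose second visit precedes the
last follow-up by at least 183 days. The study's wording is ambiguous
between "the last two visits, if they clear the buffer" and "the latest
pair that clears the buffer"; we use the latter (an eye with an early
qualifying pair is kept rather than excluded), and every exclusion is
returned with a reason so the choice is auditable.

# Numerical choices and degenerate inputs

* 8-connectivity everywhere for 2-D components (labeling is
  igraph-backed and tested against an independent flood fill).
* The Euclidean distance transform is exact (lower-envelope parabolas),
  not a chamfer approximation, and tested against brute force.
* Empty masks: area 0 with GLD reported missing; empty MNV makes the
  whole scan R3; empty regions report missing FD metrics; an empty slab
  or all-zero A-scan is flagged, not silently filled.
* Zero-variance images are an error for the adaptive FD threshold (the
  fixed strategy still applies).
* Degenerate SDs collapse the pooled-t CI to the point difference.
* Seeded generators restore the caller's RNG state.

# Problem sizes used in validation

Module tests run on 3–6-mm-equivalent grids (up to 300 x 300 px at 12-um
pitch) and choroid stacks of ~150 x 150 x 120 voxels at 40-um lateral /
4-um axial pitch; the acceptance checks use 20 seeds for FD% and VSD
recovery, 5 cylinder-phantom seeds for CVI/MCT, and 500 replications x
2000 resamples for bootstrap coverage. These sizes were chosen so each
recovery property runs in seconds to tens of seconds while keeping >= 40
pixels across every structure whose geometry matters (deficit diameters,
ring widths, bump sigmas).

# Known limitations

* Segmentation substitutes (MNV detection, artifact removal, vessel
  binarization constants) are transparent re-implementations of
  published-but-unprinted algorithms; they are validated on phantoms
  only, and real-image behaviour may differ.
* Phantom speckle and optics are deliberately simple (no PSF, no
  correlated speckle, no motion artifacts).
* VSD inherits the endpoint/junction bias of any thinning-based skeleton
  length; comparisons between groups are unaffected (same bias), but
  absolute centerline densities are a few percent low.
* The cohort generator matches marginal moments, not the correlation
  between biomarkers within an eye.
* No multiplicity adjustment, regression modeling, or longitudinal
  registration: the statistics layer deliberately stops at descriptive
  summaries and CIs, as the study did.
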