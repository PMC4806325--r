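---
title: "Methods: feature definitions, phantom design and concordance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature definitions, phantom design and concordance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`radrepro` measures whether CT radiomic features survive a repeat scan.
This vignette documents the models and conventions behind the three layers
of the package — the feature engine, the synthetic repeat-scan phantom and
the concordance analysis — together with the numerical choices that were
genuinely open and how they were settled.

## 1. The measurement model

Every feature is a function of a `voxel_grid` (a 3D array of Hounsfield
units with per-axis spacing in mm, axis order z, y, x) and an aligned
binary `segmentation_mask`. The study design crosses three reconstructed
slice thicknesses (1.25, 2.5, 5 mm) with two reconstruction kernels, sharp
("lung", L) and smooth ("standard", S); each subject is scanned twice under
fixed anatomy. Reproducibility of a feature is Lin's concordance
correlation coefficient across subjects between scan 1 and scan 2,

$$\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},$$

with population (1/n) variances — the population form is pinned down
deliberately because cohorts are small enough (n ≈ 30) for the 1/n versus
1/(n−1) choice to move the third decimal. A feature with $\rho_c \ge 0.85$
counts as reproducible; counts are also reported at 0.90 and 0.95.

## 2. The feature registry: 89 features, 15 classes

The registry (`feature_registry()`) fixes names, class membership and
order. Class sizes: Size 3, Shape 4, Shape-Index 9, Sigmoid 3, First-order
8 (Mean/SD/Skewness/Kurtosis × 3D/2D), GLCM 17, GTDM 5, Spatial
correlation 2, Run length 11, Laws 5, Edge frequency 4, Gabor 2, Wavelet
7, LoG 8, Fractal 1 — 89 in total. Two allocation decisions deserve
comment:

* **GLCM = 17** is the classical Haralick-style list (Energy, Entropy,
  Contrast, Dissimilarity, Homogeneity, Correlation, Variance, Sum
  Average/Variance/Entropy, Difference Variance/Entropy, IMC1, IMC2,
  Autocorrelation, Cluster Shade, Cluster Prominence) with Maximum
  Probability excluded.
* **Wavelet = 7** is the retained-subband set of a standard two-level
  pyramidal DWT: the level-1 detail bands LH/HL/HH plus all four level-2
  bands. The level-1 low-pass band is not a retained subband — it is what
  gets decomposed further — and keeping it would double-count its energy.
  This choice is also what makes the class total consistent with the
  89-feature census.

### Conventions shared by the texture classes

Matrix texture classes (GLCM, GTDM, run length) operate on one shared
quantization: 64 equal-width gray levels over the in-mask min–max, the
maximum mapping to level 64 and a flat ROI collapsing to level 1. Equal-
width min–max binning makes all three classes exactly invariant under
positive affine rescaling of the intensities (a property the test suite
asserts), at the price of coupling the bin width to in-mask outliers.
Whether bins should instead be fixed in HU across settings is a genuinely
open question; per-image min–max is the package's choice and is applied
per (scan, setting).

Texture offsets are **in-plane**, accumulated over axial slices. At 2.5
and 5 mm the voxels are 4–8× longer in z than in-plane, so a 3D offset
would mix two very different physical scales; the 2D/3D distinction in the
registry is reserved for the shape and first-order classes where both
variants are computed. GLCM co-occurrences are counted symmetrically at
distance 1 for the four in-plane directions, summed over directions and
over slices with at least 16 in-mask pixels, and normalized once —
matrix summation before feature computation, which is better conditioned
than feature averaging for sparse small-ROI matrices (and is what the
brute-force oracle in the test suite reproduces). Logarithms are base 2
with 0·log 0 = 0; GTDM denominators are guarded with ε = 1e-12, so a
constant ROI reports the capped Coarseness maximum 1/ε rather than an
error.

### Geometry estimators

Surface area (Compactness denominator) and slice perimeter (Roundness
denominator) use the coarea integral of a Gaussian-smoothed indicator
(σ = 1 voxel): counting exposed voxel faces overestimates a sphere's area
by tens of percent and would push the ball's Compactness far from 1,
whereas the coarea estimator lands within a few percent (digital ball
radius 16 voxels: Compactness ≈ 1.003, Roundness ≈ 0.999). Solidity uses
the regionprops-style *convex image*: the 3D convex hull of the voxel
centers (computed by an internal quickhull) rasterized back onto the
grid, so a convex digital shape scores 1 by construction. Uni and Bi are
measured on axial slices RECIST-style: Uni is the maximal boundary-point
diameter over slices (exact search over each slice's 2D convex hull), and
Bi multiplies Uni by the maximal extent perpendicular to it on Uni's
slice.

The Shape Index is Koenderink's
$\mathrm{SI} = (2/\pi)\,\mathrm{atan}\!\left((\kappa_1+\kappa_2)/(\kappa_1-\kappa_2)\right)$
from the principal curvatures of a smoothed level set of the mask,
evaluated at surface voxels and histogrammed over 9 equal bins of [−1, 1];
umbilic points are assigned SI = sign(κ). The level-set smoothing is
σ = **1.5 voxels**: at σ = 1 the voxelization noise in the Hessian spreads
a digital ball's SI across the top two bins (bin-9 fraction ≈ 0.43), while
at 1.5 the ball concentrates properly (≈ 0.99) and a spiculated phantom
still lands far lower (≈ 0.24), so the descriptor keeps its discriminative
purpose.

The sigmoid margin model fits
$I(d) = B + A/(1 + e^{(d-d_0)/w})$ along outward surface normals (d in mm,
negative inside; the midpoint slope magnitude is A/4w). Normals come from
the gradient of the smoothed mask; each profile is centered on the
sub-voxel F = 0.5 crossing and sampled every 0.5 mm over ±4 mm. Fits are
Levenberg–Marquardt (`minpack.lm`); a fit is discarded when its RMSE
exceeds half the sampled intensity range — a normalization chosen over
RMSE/|A| so that a genuinely flat boundary (A ≈ 0) is reported as such
instead of being discarded. Features are medians over normals (30 by
default inside the pipeline).

The fractal dimension is box counting on the 26-connected surface voxel
set at box sizes 1, 2, 4, 8 voxels, FD = −slope of log₂N against log₂ε.
With a 6-connected (thinner) surface the smallest box size undercounts and
a smooth ball reads ≈ 1.83; the 26-connected set restores FD ≈ 2 for both
the ball and the cube. Because the phantom's spiculation is a *low-order*
spherical-harmonic perturbation, it leaves the surface smooth at box
scales and does not measurably raise FD — FD separates rough from smooth
surfaces, not lobulated from round ones.

Degenerate ROIs (single-pixel slices, too-small bounding boxes, absent
interior pixels) return `NA` with a recorded reason; no operator crashes
or silently reports 0.

## 3. The synthetic repeat-scan phantom

The phantom generator exists so that every stage of the pipeline is
testable without patient data. It emulates, deliberately at desk scale:

* **anatomy** — a lung-like background at −850 HU with a mild correlated
  texture (SD 40 HU), a tumor at 0 HU whose interior is a Gaussian random
  field (default SD 80 HU, Gaussian correlation length 2 mm), an optional
  low-order spherical-harmonic radial spiculation and an optional
  soft-tissue vessel tangent to the tumor;
* **repeat acquisition** — anatomy is fixed (the repeat scan happens
  minutes later); scans differ by a rigid translation drawn per scan
  (SD 1 mm per axis) and independent white noise (SD 20 HU);
* **reconstruction** — the master grid is isotropic at 0.625 mm so the
  three thicknesses are exact z-slabs of 2/4/8 voxels (slab mean for the
  volume, majority vote for the mask). Kernels are modeled in image
  space: smooth = in-plane Gaussian blur (σ = 1 mm); sharp = unsharp
  enhancement I + α(I − blur), α = 1, which amplifies detail *and* noise.

This reproduces the physics the concordance analysis cares about — shared
anatomy between repeats, independent noise realizations, and a
kernel-dependent sharpness/noise trade-off whose high-frequency energy
ordering (sharp > smooth at fixed thickness, decreasing with thickness) is
asserted by the test suite. It does **not** model projection-domain CT
(beam hardening, dose, kVp/mAs), in-plane resampling, lung structure, or
segmentation error beyond the rigid shift, so passing tests say the
*analysis machinery* behaves correctly under the stated statistical
structure — not that any particular CCC value transfers to patient data.
One visible desk-scale artifact: at 5 mm thickness the tumor rim's partial
volume dominates in-mask variance, so the raw intensity SD ordering
between kernels can invert there even though the high-frequency ordering
holds.

Cohort generation draws per-subject parameters uniformly from ranges
chosen to mimic a lung-cancer cohort at this grid scale: radius 6–14 mm,
texture SD 60–120 HU, correlation length 1.5–3 mm, spiculation 0–0.25,
vessel present with probability 0.5. All stages are seeded; a cohort is
byte-reproducible from its seed.

## 4. Concordance analysis

`ccc_matrix()` computes one CCC per (feature, comparison): six
identical-setting comparisons (scan 1 vs scan 2 at the same setting) and
three cross-kernel comparisons (scan 1 sharp vs scan 2 smooth at equal
thickness). Undefined feature values drop pairwise; a comparison needs at
least 3 complete subject pairs.

**Outlier screening** is an explicit, logged policy rather than a manual
removal: with `"dixon-screen"`, Dixon's Q (two-sided, α = 0.05, tabulated
critical values for n = 3..30) is applied to the per-subject paired
differences of each feature, and the flagged subject (at most one, by
construction of the test) is removed for a screened CCC reported alongside
the raw one. Per-subject paired differences are the chosen operational
reading; the alternative quantities (ratios, CCC residuals) would need a
different justification.

**CCC comparisons** (e.g. 3D Compactness vs 2D Roundness) use a paired
subject bootstrap: resample subjects with replacement, recompute both
CCCs, and report the two-sided percentile p-value for Δ ≠ 0 (2000
resamples, seeded). No multiple-testing correction is applied anywhere,
and the output metadata says so.

`summarize_cutoffs()` counts features at the 0.85/0.90/0.95 cut-offs per
comparison (NA counts as non-reproducible; percentages are of 89, rounded
to integers); `export_heatmap()` writes the 89 × 9 CCC matrix in registry
order with empty (not zero) cells for undefined values, and
`autoplot()` renders it with a monotone red scale.

## 5. Reproducibility engineering

A single master seed fans out to documented stage seeds (cohort = seed,
bootstrap = seed + 500; per-subject and per-scan streams are derived
offsets). All CSV output uses a fixed 10-significant-digit format and
carries the registry version and a configuration hash in a leading comment
line, so identical configurations reproduce every file byte for byte —
asserted end-to-end in the test suite. Problem sizes used by the checks:
the qualitative test-retest findings (volume CCC > 0.95 at every identical
setting; matrix-texture CCC lower across kernels than within) are computed
on a 30-subject cohort — the size a same-day repeat-scan study plausibly
reaches — over all 6 settings × 2 scans; byte-determinism is asserted on a
3-subject cohort; oracle equivalences run on ≤ 8×8 fixtures.

## 6. Known limitations

* The kernel model is an image-space surrogate; real reconstruction
  kernels shape the noise power spectrum in ways unsharp masking only
  approximates qualitatively.
* Per-image quantization means texture features are scale-free but not
  comparable in absolute terms across studies that quantize with fixed HU
  edges.
* The Edge-Frequency class's Coarseness is a distinct quantity from GTDM
  Coarseness (an inverse mean gradient magnitude, normalized so a constant
  image scores 1); the two should not be conflated when comparing against
  other implementations.
* Dixon's Q is undefined above n = 30; larger cohorts get a flagged
  no-op rather than a silently different test.
* 2D features depend on the largest-slice choice; ties break to the
  smallest slice index, which is deterministic but arbitrary.
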