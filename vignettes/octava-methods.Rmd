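---
title: "Methods: vascular quantification and VA estimation in octava"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vascular quantification and VA estimation in octava}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octava)
```

`octava` quantifies en-face macular OCTA angiograms — foveal avascular zone
(FAZ) area and skeleton vascular density (VD) per ETDRS grid zone in the
superficial and deep capillary plexuses — and estimates decimal
best-corrected visual acuity (BCVA) from those biomarkers. This vignette
records the model, its assumptions, the tunable parameters, the numerical
choices, and what the synthetic validation does and does not establish.

## Image model and conventions

An angiogram is a square grid of 8-bit intensities with physical extent
`extent_mm` (3 or 6 mm in routine macular protocols, but any size is
accepted: device export resolutions vary, so the pixel pitch is always
carried as metadata rather than assumed). Row 1 is the superior edge, column
1 the left edge, and pixel `(i, j)` has its center at `(i − 0.5, j − 0.5)`;
all geometric predicates (grid membership, distances, centroids) use pixel
centers, which makes boundary behavior unambiguous. Bright pixels are flow
signal; this polarity is fixed, matching how OCTA devices render
angiograms. RGB files whose channels are identical are collapsed — exported
screenshots are often RGB — but truly colored input is rejected rather than
silently converted, since a color map would destroy the intensity scale.

## Vessel segmentation

Otsu's criterion selects the binarization threshold from the 256-bin
histogram: the chosen *t* maximizes the between-class variance
$\sigma^2_b(t)$, equivalent to maximizing the ratio
$Q(t) = \sigma^2_b(t)/\sigma^2_w(t)$ because
$\sigma^2_b(t) + \sigma^2_w(t)$ is the fixed total variance. The
implementation maximizes $\sigma^2_b$ directly — the ratio form divides by
zero whenever a candidate class is internally constant (e.g. a two-level
image) — and reports both components plus `Q`; a property test asserts the
decomposition to 1e−9 relative. Ties are broken toward the smallest
threshold, matching common reference implementations; images with fewer
than two gray levels are a degenerate-input error, since no threshold
partitions them. Foreground is *strictly* above *t*. No despeckling or
smoothing precedes thresholding in the density branch: the synthetic and
clinical intensity distributions are strongly bimodal and the skeleton
statistic is robust to isolated misclassified pixels.

Skeletonization is the classic two-subiteration parallel thinning
(Zhang–Suen): contour points are deleted simultaneously, alternating
south-east and north-west passes, each deletion requiring 2–8 neighbors,
exactly one 0→1 transition around the pixel (so connectivity is preserved),
and the pass-specific edge conditions, until convergence. The
implementation was verified pixel-for-pixel against an independent,
literal-from-the-book reimplementation. Two cautions are documented rather
than patched: the classic algorithm erodes free line ends by one to two
pixels (a 3×20 bar thins to a 17-pixel midline), and certain contrived
configurations (an isolated 2×2 square; a 2×2 square with four diagonal
tails) are not thinned the way a lookup-table variant would. Neither
arises in capillary networks, and the invariants — skeleton ⊆ mask, no 2×2
all-ones block, idempotence, component-count preservation — are enforced by
tests on one hundred generated fixtures.

## FAZ segmentation

The FAZ detector runs only on 3×3 mm superficial-plexus scans (the deep
plexus FAZ is never computed; the estimator's feature set uses the SCP FAZ
alone). Stages, with defaults:

1. **Smoothing**: Gaussian, `smooth_sigma_px = 2` px, separable with
   renormalized edges. This stabilizes the subsequent threshold against
   speckle.
2. **Vascular edges**: Otsu mask of the smoothed image, then morphological
   closing with a disk of `close_radius_px = 2` px to seal capillary gaps
   that would let the avascular region bleed into inter-capillary space.
3. **Candidates**: 8-connected components of the closed mask's complement.
   Components touching the image border are discarded — the FAZ is an
   interior structure, and the border band outside the scanned vasculature
   would otherwise masquerade as a huge "avascular" region.
4. **False-positive filters** (all configurable in `faz_config()`): area
   within `[0.05, 2.0]` mm² (brackets FAZ areas reported across healthy and
   diseased eyes), centroid within 1/3 of the half-width from the frame
   center (captures are fovea-centered by protocol), compactness
   $4\pi A/P^2 \ge 0.2$ with the perimeter estimated as exposed pixel-edge
   count (for a digital disk this estimator gives ≈ 0.62, so 0.2 admits
   irregular ischemic FAZs while rejecting filament-shaped false
   positives).
5. **Selection**: the survivor minimizing
   `distance/halfwidth − 0.25 × compactness` — a deterministic
   scalarization of "central and FAZ-shaped".
6. **Refinement**: the smoothed mask localizes robustly but the blur widens
   vessels by O(σ) pixels, which would shave the avascular rim by a
   resolution-dependent margin (measured: −3 to −7% area bias). The final
   boundary is therefore re-extracted from the *unsmoothed* Otsu vessel
   mask: the background component under the candidate centroid replaces the
   candidate, unless its area differs by more than ±50% (a leak through a
   capillary gap the smoothing had sealed, or a speckle at the centroid),
   in which case the smoothed candidate is kept. This removed the bias
   entirely on synthetic ground truth (median error 0) while keeping the
   smoothed stage's robustness.
7. Holes are filled (interior speckle must not reduce the area) and the
   area is `pixel count × scale²`.

If no candidate survives, a detection-failure error is raised; callers such
as the cohort pipeline log it and exclude the visit. Detection is fully
deterministic.

## ETDRS grid and zonal density

The grid is the standard macular layout: a 1 mm diameter foveal disk and a
3 mm diameter outer ring whose annulus is split into four quadrants by the
±45° diagonals. Pixels on a diagonal are assigned by half-open angular
intervals (upper = [45°, 135°), measured from image-right,
counterclockwise), so the five masks always partition the outer disk
exactly — an identity the tests assert pixel-for-pixel. Laterality decides
the horizontal labels: for OD (right eye) the nasal quadrant is image-right.
This follows from en-face orientation: fundus-oriented imaging presents the
retina as seen through the pupil, so the right eye's nasal retina — the
side toward the nose, the patient's midline — appears on the image's right.
The OD/OS mirror identity (nasal(OD) = temporal(OS)) holds by construction
regardless of this choice.

Density restricted to a zone is `skeleton pixels in zone / zone pixel
count` — the only reading under which zone values are comparable fractions;
the whole-frame variant (`sum of pixels / (height × width)`) is reported as
`dens_global`. Two grid ambiguities on 6×6 mm scans are resolved as
follows, both overridable: the same physical 1/3 mm grid is applied (the
protocol names a single grid for both scan sizes; `grid_outer_mm`
overrides), and the grid sits at the frame center (the FAZ is only detected
on 3×3 mm scans; `center_6mm = "faz"` propagates the detected centroid
through the shared foveal frame center instead, for co-centered captures).
On 3×3 mm scans — both plexuses — the grid is centered on the detected FAZ
centroid, which is the point of measuring the FAZ first.

## VA estimation

Feature vectors are fixed-order: FAZ area (mm²), then five zone densities
for SCP 3 mm, SCP 6 mm and, in the full experiment, DCP 3 mm and DCP 6 mm —
21 features, or 11 in the SCP-only experiment. Features are z-scored with
training-set statistics (FAZ area in mm² and densities in [0, 1] live on
incompatible scales; fitting the scaler on training folds only avoids
leakage). The regressor is epsilon-SVR whose dual is solved exactly as a
quadratic program (`quadprog`), with a tiny ridge (1e−8 × mean kernel
diagonal) for strict positive-definiteness; the bias is recovered from the
free support vectors' KKT conditions. Defaults: linear kernel (the
biomarker–VA relationship is modeled as a hyperplane; an RBF kernel is
available), `C = 1`, `epsilon = 0.05` — half a decimal acuity line, the
measurement granularity of a VA chart. Predictions are clipped to [0, 1],
the decimal VA range. The epsilon tube implies residuals up to epsilon even
on noiseless data; where an analysis targets a known noise level σ, epsilon
should be set commensurate with σ (the package's noiseless recovery checks
use `epsilon = 1e-3` for exactly this reason).

Evaluation is seeded k-fold cross-validation (default k = 5): a uniform
shuffle into folds whose sizes differ by at most one (n = 133 gives
27/27/27/26/26), out-of-fold predictions pooled, then Pearson r with the
t-transform p-value and MSE on the decimal scale. A patient's repeated
visits are *not* grouped into one fold by default — mirroring the simple
stated procedure — but `group_by_patient = TRUE` provides the leakage-safe
variant. The model is also refit on all data and its in-sample MSE
reported: the train-vs-held-out gap is itself informative (the optimistic
whole-sample number is what subgroup breakdowns use, and the tests assert
it is no larger than the held-out MSE in expectation). logMAR conversion is
`−log10(VA)`, defined for VA > 0 only.

## The synthetic world

The generator renders what the validation needs and no more: a jittered
rectilinear capillary lattice (bright 180–255 on dark 0–60 — clearly
bimodal, so thresholding behavior is predictable), an avascular disk
bounded by a drawn perifoveal arcade ring whose inner edge sits exactly at
the nominal radius (as in the retina; without the ring the "true" avascular
area would be ill-defined at the half-lattice-spacing scale), per-zone
dropout of inter-junction segments emulating capillary non-perfusion, and
additive Gaussian intensity noise. Cohort VA follows a known linear law
over the 21 ground-truth biomarkers — signs encode the clinical
expectations (VA falls with FAZ enlargement, rises with perfusion), and the
weights are scaled so the noiseless VA signal has sd ≈ 0.16 about a mean of
0.5, keeping the law effectively unclipped in [0, 1] and the vascular
signal dominant over a σ = 0.05 measurement noise. The disk-level default
of 12 px lattice spacing at 320 px/3 mm corresponds to ≈ 110 µm capillary
spacing and yields skeleton densities around 0.15, within the range
reported for macular plexuses.

What a green test does *not* establish: the lattice is not a branching
vascular tree, has no projection or motion artifacts and no speckle
statistics, and the VA law is linear by construction — so the validation
demonstrates correct recovery of known geometry and a known law, not
clinical accuracy. The study that motivated this package evaluated its
method on 133 undeposited patient scan sets; those headline correlations
are not reproducible here, which is why the package's acceptance checks are
property-based throughout.

## Numerical and degenerate-input choices

- Otsu: smallest-argmax tie rule; degenerate (constant) images error.
- Thinning: iterate to a fixed point; output verified idempotent.
- Geometry: pixel-center membership everywhere; half-open angular
  intervals; the ETDRS partition is exact by construction, not by
  tolerance.
- FAZ: refinement guarded by the ±50% area-ratio check; failure to detect
  is an error, never a silent zero.
- SVR: exact QP (no iterative tolerance beyond the ridge); seeded fold
  shuffles restore the caller's RNG state afterwards.
- All file outputs (`metrics.json` etc.) are written with full precision,
  so a fixed seed reproduces runs byte-identically.

## Known limitations

- The FAZ candidate filters are engineering defaults validated on synthetic
  recovery only; strongly ischemic, non-compact FAZs near the filter
  boundaries may be rejected (tiny FAZs below 0.05 mm² are, by design).
- Densities use the skeleton statistic only; perfusion-area density and the
  device's internal flow metric are out of scope.
- The estimator does not search hyperparameters; C, epsilon, and the kernel
  are configuration, and reported errors are conditional on them.
- 6×6 mm grid handling (same physical grid, frame-centered) is one of two
  defensible readings of the protocol; both are exposed as options.
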