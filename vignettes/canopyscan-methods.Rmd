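---
title: "Methods: low-cost multi-view plant phenotyping with canopyscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-cost multi-view plant phenotyping with canopyscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyscan)
```

# The problem

Manual measurement of plant architecture is destructive and slow, which is
why whole-growth-period phenotyping of individual plants (here: potted
soybean imaged on a motorized turntable) is attractive to do photographically.
`canopyscan` implements the complete chain: calibrated multi-view imaging of
one plant against a blue screen, reconstruction of a coloured 3D point cloud
and a watertight mesh, extraction of six canopy traits, and analysis of
their whole-season time courses with a logistic growth model and normalized
"phenotypic fingerprint" matrices.

The imaging geometry is a camera on a vertical rail viewing a plant on a
turntable: four elevation rings between 10 and 25 degrees, fifteen stops per
revolution, sixty views per plant. All world coordinates are centimetres
with z up and the turntable centre at the origin; pixel coordinates have
their origin at the top-left corner with pixel centres on integers.

# Camera model and calibration

The camera is the classical pinhole model `s m = K [R t] M` with intrinsics
`fx, fy, u0, v0`. Lens distortion is decomposed into radial, centrifugal and
thin-prism parts; the full displacement model (`distort_forward()`) exists
for simulation, but the *correction* path is radial-only,

$$u_d = u + k_1 (u - u_0) r^2, \qquad v_d = v + k_1 (v - v_0) r^2,$$

with $r^2$ taken from the normalized coordinates — non-radial distortion is
an order of magnitude smaller than radial for ordinary lenses and is
deliberately not corrected. The inverse map (`radial_undistort()`) is not
given in closed form by the model; we invert by fixed-point iteration (40
iterations maximum, stop at 1e-10 normalized units). A 1e-8 stop turned out
to leave errors of a few millionths of a pixel (~5e-6 px) at image corners for
$|k_1| = 0.2$, which is why the tolerance is tighter than one might first
pick.

Calibration uses a planar mat of 15 radial groups of 4 dots (60 points on
z = 0). The published mat's exact geometry (ring radii, dot size, group
spacing) is not available, so the built-in `calibration_target()` is a
documented synthetic stand-in: groups at a 24-degree pitch spanning two
concentric ring bands, plus four oversized corner fiducial markers that are
*not* part of the 60-point pattern. The fiducials exist to make dot
*identification* trivial: the four largest dark blobs define a homography
(their corner assignment is disambiguated geometrically by trying all eight
square symmetries and keeping the one that matches the most dots), and every
nominal dot is transferred through it to the nearest detected centroid.
Centroids are sub-pixel (binary blob means) and land within 0.5 px of the
true projections on rendered fixtures.

`calibrate_ransac()` estimates `fx, fy, u0, v0, k1` and one pose per view:

1. per view, a RANSAC homography (minimal sample 4, default 1000 iterations,
   2 px transfer-error threshold, fixed seed 42 — all configurable) with a
   DLT refit on the inliers;
2. closed-form intrinsics from the inlier homographies (the skew estimate is
   discarded; the model has none);
3. pose recovery per view from each homography;
4. joint Levenberg–Marquardt refinement of all parameters on the inlier
   reprojection residuals under the radial model. Two passes are run: after
   the first, inliers are *reclassified* under the refined distortion model
   and the fit repeated. Without the second pass, strongly distorted rim
   points stay flagged as homography-stage outliers and `k1` becomes
   unidentifiable.

Two geometric caveats that the tests encode: planar calibration degenerates
when all views share one tilt (a single turntable ring azimuth sweep adds no
constraint), so calibration fixtures photograph the mat at several tilts;
and `k1` is only observable when the mat reaches the image periphery, so
distortion-recovery fixtures use close-up views.

# Image preprocessing

Turntable photographs are denoised per channel by a separable Daubechies-4
wavelet decomposition (3 levels, periodic boundary, symmetric padding to a
multiple of $2^L$) with soft thresholding of all detail bands at the
universal threshold $\sigma\sqrt{2\ln n}$, $\sigma$ estimated as
MAD/0.6745 of the finest diagonal band — the standard treatment when the
contaminating noise is white and Gaussian. No other noise model is
implemented. Since no wavelet package ships with the supported R stack, the
transform is implemented directly; the synthesis step is the exact adjoint
of the analysis step, so reconstruction is exact to rounding.

Blue-screen segmentation calls a pixel background iff `B > R + tau` and
`B > G + tau` (default `tau` = 30 of 255; strictly greater, so a pixel at
exactly `tau` dominance stays foreground). Cleanup is a 3x3 morphological
opening followed by removal of connected components under 100 px (both
defaults configurable, cleanup skippable). On rendered fixtures the cleaned
mask overlaps the true silhouette with IoU above 0.98.

# Multi-view reconstruction

Interest-point detection and descriptor matching (SURF in the original
pipeline) are deliberately *pluggable*: `build_cloud()` takes any
`detector(images, masks, cameras)` function returning pixel
correspondences, and the synthetic renderer exports exact dot
correspondences that play this role in tests. The package's own
contribution starts after matching:

* correspondences are restricted to the foreground masks of both views;
* the epipolar constraint filters mismatches. With calibrated cameras the
  fundamental matrix is *derived* (`F = [e2]x P2 P1^+`), not estimated; the
  symmetric epipolar distance (max of the two point-line distances) must
  stay under the threshold (default 1 px). An uncalibrated RANSAC
  eight-point mode exists for the no-calibration path (2000 iterations,
  fixed seed);
* inliers are triangulated linearly (DLT; the batch path solves the
  equivalent inhomogeneous normal equations in closed form), points behind
  either camera or reprojecting worse than the threshold are dropped;
* duplicates are merged on a 0.1 cm voxel grid (centroids; colors and
  normals averaged).

All pairwise consecutive same-ring view pairs are fused; with the default
rig that is 60 pairs.

# Poisson surface reconstruction

The oriented cloud is turned into a watertight mesh by solving the Poisson
problem $\nabla^2\varphi = \nabla\cdot\vec V$, where $\vec V$ is a smoothed
version of the surface-normal field:

* **Octree.** `build_octree()` refines sample-bearing nodes of the padded
  bounding cube to depth D. The linear system itself is assembled on the
  *complete* depth-D node grid ($2^D$ cells per axis): adaptive conforming
  bases (screened Poisson) are out of scope, and at the depths used here
  (4–6) the complete grid is affordable and simpler to reason about.
* **Basis.** Node functions are translates/dilates of a base profile built
  from box-filter convolutions. The text we follow leaves the base filter
  implicit and its neighbour-weight prescription is internally inconsistent
  (8 neighbour nodes with cubic-spline weights — cubic support needs 64);
  we adopt the standard resolution: a tri-*quadratic* B-spline basis (three
  box convolutions, 3-cell support, unit integral), trilinear 8-node
  splatting by default, tricubic 64-node splatting behind a flag. Per-sample
  splat weights sum to exactly 1 (partition of unity), which a test asserts.
* **Galerkin system.** Stiffness and load use separable 1D inner products
  of the B-spline and its derivative, computed once by quadrature and
  combined as tensor products. The outermost node layer is clamped to
  $\varphi = 0$ (the bounding cube is padded by a factor 1.3, so the surface
  stays away from the boundary); this anchors the otherwise singular Neumann
  system.
* **Solver.** Gauss–Seidel sweeps in natural order (`gauss_seidel_solve()`,
  CSR kernel in C++), relative-residual tolerance 1e-8, budget 10,000
  sweeps; convergence is guaranteed for these SPD systems, and a test checks
  agreement with a dense direct solve to 1e-8 on random SPD systems up to
  500x500.
* **Isosurface.** The isovalue is the mean of $\varphi$ over the input
  samples (the standard convention; the text does not state one). Each grid
  cell splits into six tetrahedra sharing the main diagonal; the sign
  pattern on each tetrahedron emits 0–2 triangles with vertices linearly
  interpolated along crossing edges, and shared vertices are welded by edge
  key, so the mesh is deterministic given the cloud.

On a 2000-sample sphere of radius 10 cm at depth 5, the reconstruction's
RMS radial error is a few hundredths of a cm (well under the 0.8 cm leaf
cell) and the mesh area is within 1% of $4\pi R^2$.

Clouds without normals get them from PCA over 16 nearest neighbours with
orientation propagated along a Euclidean minimum spanning tree, then
globally flipped outward; synthetic fixtures carry analytic normals so this
path is tested separately.

# Trait extraction

Six traits per plant, with the cotyledon node (the stem node where the seed
leaves attached) as the zero reference for heights:

* **plant length / width** — sides of the minimum circumscribed rectangle of
  the cloud's ground-plane projection (rotating calipers over hull edge
  directions; length is the longer side);
* **canopy height** — cotyledon node to the highest point of the plant;
* **plant height** — cotyledon node to the stem growing point. In a raw
  cloud the growing point is indistinguishable from leaf tops, so we use a
  stem-axis heuristic: the axis is the vertical line through the centroid of
  the lowest 10% of points, and the apex is the highest point within a 2 cm
  cylinder around it. On synthetic fixtures (where leaves are kept clear of
  the axis) the distinction is exact;
* **canopy area** = length x width (cm^2), and **plant volume** = length x
  width x canopy height / 1000 (dm^3) — defined products, asserted exactly.

When the cotyledon height is not supplied, it is estimated as the base of
the lowest height slice (0.1th percentile). A 1st-percentile cut, the first
thing one might try, sits about 2 cm up the stem at realistic sampling
densities (a quarter of the points on a ~50 cm stem) and misses the node by
more than the 0.5 cm we require of the estimator.

# Growth analysis

Each trait's season course is fitted with the 3-parameter logistic curve

$$N(t) = \frac{K}{1 + (K/N_0 - 1)e^{-rt}},$$

`t` in days after seedling emergence, by gradient descent on
log-transformed parameters (positivity for free), observations scaled by
their maximum, learning rate 1e-2 with halving on any RSS increase, budget
50,000 iterations. Initialization: $K = 1.05\max y$, $N_0 = y_1$, $r$ from
the slope of $\mathrm{logit}(y/K)$ against $t$. A Levenberg–Marquardt
refinement exists behind `refine = TRUE` but is off by default so plain
gradient descent is the default estimation path; on the study conditions it
reaches the same optimum (RSS agreement ~1e-7), so the flag matters only
for pathological series. The rate curve is $dN/dt = r(1-N/K)N$, maximal at
$N = K/2$, i.e. at $t^* = \ln(K/N_0-1)/r$ (reported both exactly and
rounded to whole days); fits with $K \le 2N_0$ have their inflection before
emergence and are flagged. "Highest value" of a trait is reported two ways —
the asymptote `K` and the fitted value at the last observed day — because
printed seasonal maxima can be either.

Under the study's own noise level (sigma = 2% of K at nine time points) the
asymptote is recovered to ~0.6% median absolute error, but the early-season
parameters $N_0$ and $r$ have noise-driven absolute spreads of several
percent for *any* least-squares estimator; what holds (and what the tests
assert for them) is near-unbiasedness — median signed errors under 3%.

Fingerprint matrices normalize the four radar-chart traits (plant height,
length, width, canopy height) to [0, 1] by the global per-trait maximum
over all varieties and stages, so each trait column attains 1 somewhere;
per-stage normalization is available by flag. Accuracy versus reference
measurements uses `pearson_r()`, and field-versus-barrel comparisons use
the two-sided Welch t-test — both thin wrappers over the corresponding
stats-package routines, kept as named operations of the analysis surface.

# Synthetic fixtures: what they emulate, and what they do not

`make_plant_cloud()` builds a parametric potted plant with *exact* trait
ground truth: a 0.5 cm-radius stem from the cotyledon node to the apex,
four ellipsoidal leaf lobes whose outermost points are pinned on the
footprint corners (so the minimum rectangle is exactly the specified
footprint), one top lobe pinned on the canopy top, and optional interior
lobes. Lobes are kept above 45% of the canopy span so the lowest tenth of
the cloud is stem-only (bare lower stem, as on a real plant) and clear of a
2 cm axis cylinder above the apex. `render_views()` is a z-buffered point
splatter on a blue background — sufficient for silhouette, correspondence
and calibration fixtures; it has no shading, self-shadowing, botanical
branching, leaf texture or specularity, so passing tests demonstrate the
*geometry* chain, not robustness to photometric effects or to real
descriptor matching (the matcher is pluggable and out of scope).
`make_growth_series()` evaluates the logistic curve at nine observation
days spanning the season — emulating determinations at the stages V3–R8 —
and adds Gaussian noise scaled to K, clipping at zero.

The end-to-end check (`synthetic_validation()`) renders ten plants with
footprints 25–55 cm, canopies 35–75 cm and varied leaf counts through the
full 60-view rig at 320x240, segments, reconstructs and extracts traits;
Pearson correlations between extracted and true values exceed 0.99 for all
four fingerprint traits. Problem sizes throughout (8000 surface samples,
320x240 renders, depth-5 sphere, 200 recovery replicates) were chosen so
the whole validation runs in minutes on one core while keeping every
estimate comfortably inside its tolerance.

# Numerical choices and degenerate inputs

* Projection refuses points on the principal plane (|z| < 1e-12).
* Rotations are validated to 1e-9 (orthonormality and det +1); poses from
  homographies and look-at constructions are re-orthonormalized by SVD.
* The minimum-rectangle brute-force oracle (0.01-degree angle sweep) is an
  *upper* bound on the true minimum with error of order the grid step;
  tests therefore assert that rotating calipers never exceeds it (to 1e-6
  relative) rather than two-sided equality, which no correct implementation
  could meet.
* Gauss–Seidel errors out on a zero diagonal and warns (returning the
  residual) when the sweep budget runs out.
* Marching tetrahedra on a constant-sign field returns an empty mesh, not
  an error; degenerate interpolation (equal corner values) falls back to
  the edge midpoint.
* All randomness flows through explicit seeds (RANSAC default 42; fixture
  generators take seeds); no function mutates the caller's RNG state.
* Merging with voxel 0 is the identity; segmentation cleanup is skipped for
  images smaller than the structuring element.

# Known limitations

* The pipeline reconstructs from supplied correspondences; no SURF-style
  detector ships with the package, so real-photo reconstruction requires an
  external matcher behind the detector interface.
* The Poisson solve uses the complete depth-D grid; memory grows as $8^D$
  and depths above ~7 are impractical in this implementation.
* Plant height relies on the stem-axis heuristic and degrades when leaves
  overhang the stem apex within the 2 cm cylinder.
* Trait extraction assumes the vertical axis is known (turntable frame);
  no gravity estimation is attempted.
* The growth model is logistic-only by design; alternative growth laws
  (Gompertz, Richards) and mixed-effects formulations are out of scope, as
  is multiple-testing correction across t-test grids.
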