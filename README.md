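# canopyscan

Low-cost multi-view 3D plant phenotyping and whole-growth-period analysis
in R.

Breeders and crop physiologists who want non-destructive, season-long
measurements of individual plants (the motivating system is potted soybean)
can photograph a plant on a motorized turntable — four camera elevations
between 10° and 25°, fifteen stops per revolution, sixty views — and let
`canopyscan` carry the images all the way to trait time-series analysis:

1. **Camera calibration** — pinhole model `s·m = K[R t]M` with radial
   distortion `u_d = u + k1(u−u0)r²`, calibrated from a planar radial dot
   mat (15 groups × 4 dots) by Zhang-style initialization inside a RANSAC
   loop and joint Levenberg–Marquardt refinement.
2. **Preprocessing** — Daubechies-4 wavelet denoising with the universal
   threshold σ√(2 ln n), and blue-screen segmentation
   (background ⇔ B > R + τ and B > G + τ).
3. **Reconstruction** — epipolar filtering of correspondences (the interest
   point detector/matcher is pluggable), DLT triangulation, voxel merging;
   then Poisson surface reconstruction: octree, tri-quadratic B-spline
   basis, Gauss–Seidel solve of ∇²φ = ∇·V̄, marching-tetrahedra isosurface.
4. **Traits** — plant length and width (sides of the minimum circumscribed
   rectangle of the ground projection, by rotating calipers), plant height
   and canopy height (from the cotyledon node), canopy area = length ×
   width, plant volume = length × width × canopy height / 1000 (dm³).
5. **Growth analysis** — per trait and variety, the 3-parameter logistic
   model N(t) = K / (1 + (K/N0 − 1)e^(−rt)) fitted by gradient descent;
   growth-rate curves dN/dt = r(1 − N/K)N with the maximum rK/4 reached at
   t\* = ln(K/N0 − 1)/r; normalized "phenotypic fingerprint" radar
   matrices; Pearson-r accuracy checks and Welch t-tests.

A synthetic-fixture module generates every input with exact ground truth:
parametric plants, rendered calibrated turntable views (plant and
calibration mat), and noisy logistic trait series.

## Worked example

Reconstruct a synthetic plant through the full rig and compare the
extracted traits with the generator's ground truth:

```r
library(canopyscan)

plant <- make_plant_cloud(plant_spec(footprint_length_cm = 40,
                                     footprint_width_cm = 30,
                                     canopy_top_cm = 60,
                                     cotyledon_cm = 5, seed = 11), n = 8000)
K   <- intrinsics(400, 400, 160, 120, width = 320, height = 240)
rig <- turntable_rig()                       # 4 rings x 15 stops = 60 views
rs  <- render_views(plant$cloud, rig, K, seed = 3)
masks <- lapply(rs$images, segment_blue_screen)
cloud <- build_cloud(rs$images, masks,
                     list(intr = K, views = rs$poses),
                     ground_truth_detector(rs))
extract_traits(cloud, ground_frame(cotyledon_height_cm = 5))
```

```
  variety stage days plant_length_cm plant_width_cm plant_height_cm
1    <NA>  <NA>   NA              40             30              53
  canopy_height_cm canopy_area_cm2 plant_volume_dm3
1         54.78285            1200         65.73942
```

The generator's truth is length 40 cm, width 30 cm, plant height 53 cm,
canopy height 55 cm, area 1200 cm², volume 66 dm³ — every trait is
recovered within 0.5%. Fitting a season of plant-height observations:

```r
days  <- c(10, 20, 30, 40, 55, 70, 85, 100, 115)
s     <- trait_series("DN", "plant_height_cm", days,
                      logistic_value(list(n0 = 8, k = 85, r = 0.12), days))
fit   <- fit_logistic(s)
fit
```

```
logistic fit [DN / plant_height_cm]: N0=8  K=85  r=0.12 1/day
  RSS=1.034e-07  t*=18.87 days  max rate=2.55 /day  fitted max=85
```

`max_rate_time(fit, round_days = TRUE)` gives the day the growth rate
peaks (19 here), the quantity used to time field management per variety.

A command-line interface wrapping the same functions ships in
`inst/cli/canopyscan.R` (subcommands `calibrate`, `segment`, `reconstruct`,
`mesh`, `traits`, `growth`, `fingerprint`, `simulate`, `run`), and
`run_pipeline()` executes the whole chain from a validated JSON
configuration, writing `cameras.json`, masks, `cloud.ply`, `mesh.obj`,
`traits.csv`, `fits.json` and `fp.csv`.

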