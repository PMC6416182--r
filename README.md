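# maizeskel

Curve-skeleton extraction and phenotypic trait estimation from 3D point
clouds of maize plants.

Organ-level maize phenotyping needs the one-dimensional structure hidden in
a laser-scanned plant: the stem axis and one midrib (vein) curve per leaf.
`maizeskel` turns a colored point cloud of a single plant (PLY, PCD or
plain `x y z r g b` text) into that semantic curve skeleton and tabulates
six traits from it — per leaf the length, inclination angle, top length,
azimuth angle and growth height; per plant the height. It is aimed at
plant-phenotyping researchers processing terrestrial-laser or
multi-view-stereo scans of individual plants.

## Method

The pipeline has five stages:

1. **Denoising** — pot points are removed by an illumination-robust color
   difference `D = 2 |max(η_i, η_j)/min(η_i, η_j) − 1| · θ` (η the channel
   mean, θ the angle between mean-centered chroma vectors scaled to 0–255;
   points with `D < 0.1` of a sampled pot color are dropped), and scanning
   clutter by radius clustering with a density-derived minimum cluster
   size.
2. **Laplacian contraction** — the cloud shrinks onto its skeleton through
   repeated constrained least-squares solves
   `[W_L L; W_H] P⁽ᵗ⁺¹⁾ = [0; W_H P⁽ᵗ⁾]` with a cotangent Laplacian `L`
   built from local tangent-plane Delaunay one-rings, `W_L ← 3 W_L` and
   `W_H,i = S_i⁰/S_iᵗ` updated from one-ring lengths each iteration.
3. **Adaptive sampling** — greedy sphere absorption reduces the contracted
   points to key points, finer where the directionality degree
   `l(v) = λ₂/(λ₀+λ₁+λ₂)` signals mixing branch directions.
4. **Topology** — degree-capped 3-nearest-neighbor connection with
   tangent-coherence filtering; closed loops are broken at the edge with
   the largest combined coplanarity + turning-angle weight
   `W = W_s/max(W_s) + W_c/max(W_c)`; the tree splits into a stem (the
   path maximizing vertical rise minus horizontal wander) and one leaf per
   off-stem subtree.
5. **Calibration** — stem sections are straightened by total-least-squares
   line fits, leaf nodes re-centered by cutting-plane slab centroids
   against the original cloud, tips recovered by marching the cutting
   plane forward, and attachments reconstructed by backward extrapolation
   of a robust quadratic onto the stem line.

A procedural maize generator (`make_plant()`, `make_study()`) provides
plants with exact analytic ground-truth skeletons and trait tables, so the
whole pipeline is validated end to end without external data. See the
vignette (`vignettes/maize-skeletonization.Rmd`) for the model details,
parameter choices and known limitations.

## Worked example

```r
library(maizeskel)

plant <- make_plant(plant_spec(seed = 7, height = 1.8,
                               points_per_plant = 10000))
plant$cloud
#> point_cloud: 11299 points
#>   bbox  x [-0.294, 0.278]  y [-0.640, 0.692]  z [-0.327, 2.003] (m)
#>   bbox diagonal 2.744 m

skel <- extract_skeleton(plant$cloud, pot_colors = plant$truth$pot_samples)
summary(skel)
#> plant_skeleton: stem of 35 nodes, 12 leaves, calibrated
#>   plant height 1.843 m; leaf lengths 0.43-0.71 m
#>   stages: input=11299, simplified=9087, denoised=7913, key_points=156, leaves=12
#>   contraction: 2 iterations, one-ring length ratio 0.177
#>   traits:
#>  leaf_rank leaf_length_m inclination_deg top_length_m azimuth_deg ...
#>          1        0.5420           56.15       0.2707       0.000
#>          2        0.5983           49.73       0.3139     187.997
#>          3        0.6550           48.92       0.4095       2.887
#>          ...
```

The 11,299 input points (plant surface + pot + clutter) are reduced to
about 9,000, cleaned to 7,913 plant points, contracted and sampled into 156
skeleton key points, and segmented into a stem and 12 leaves — the correct
count for this plant. `coef(skel)` returns the trait table; row 1 is the
lowest leaf (azimuth 0 by convention), and the alternating ~180° azimuths
show the recovered phyllotaxy. Against this plant's exact ground truth:

```r
evaluate_traits(coef(skel), plant$truth$traits)
#> trait evaluation (rank-matched leaves):
#>            trait nrmse_pct r_squared  n
#>    leaf_length_m      1.32     0.994 12
#>  inclination_deg      5.39     0.957 12
#>     top_length_m      2.11     0.987 12
#>      azimuth_deg      0.38     1.000 12
#>  growth_height_m      0.78     1.000 12
#>   plant_height_m      0.02        NA 12
```

So leaf lengths are recovered to about 1%, attachment heights to under 1%,
azimuths to a third of a degree, and plant height to 0.02% on this plant;
inclination angles, the hardest trait because every leaf's sheath region is
hidden inside the stem, come back within about 2 degrees RMS.

`plot(skel)` draws the skeleton over the cloud; `residuals(skel)` gives
each cloud point's distance to the nearest skeleton segment. A thin
command-line front end (`inst/cli/maizeskel.R`) exposes `synth`, `run` and
`eval` subcommands over the same functions.

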