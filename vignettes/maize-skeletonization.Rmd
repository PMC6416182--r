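---
title: "Curve-skeleton extraction and trait estimation for maize point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curve-skeleton extraction and trait estimation for maize point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A terrestrial laser scan of a single maize plant is a colored point cloud of
tens of thousands of surface samples. Organ-level phenotypes — how long each
leaf is, how steeply it leaves the stem, which way it points, how high it
attaches, how tall the plant is — live on a one-dimensional structure hidden
inside that cloud: the *curve skeleton*, one polyline for the stem axis and
one for each leaf midrib (vein). `maizeskel` extracts that skeleton and
derives six phenotypic traits from it.

The pipeline has five stages, run end to end by `extract_skeleton()`:

1. **Denoising.** Pot points are recognized by an illumination-robust color
   difference against a small list of sampled pot colors; scanning clutter is
   removed by radius clustering (connected components of the `<= r` proximity
   graph, `r = 0.012` of the bounding-box diagonal) followed by a
   density-derived minimum cluster size (half the mean neighborhood count at
   ten random probes).
2. **Laplacian contraction.** The cloud is iteratively shrunk onto its
   skeleton by solving the constrained least-squares system
   $$\begin{bmatrix} W_L L^t \\ W_H^t \end{bmatrix} P^{t+1} =
     \begin{bmatrix} 0 \\ W_H^t P^t \end{bmatrix},$$
   where $L^t$ is a cotangent Laplacian built from local tangent-plane
   Delaunay one-rings, $W_L$ (scalar) grows by a factor $S_L = 3$ per
   iteration and $W_{H,i} = S_i^0 / S_i^t$ tracks the per-point one-ring
   length ratio. Iteration stops when the total one-ring length decreases by
   less than 1% in a step, when a step would increase it (the step is then
   discarded), or after 20 iterations; maize clouds typically collapse in
   two to four.
3. **Adaptive sampling.** The contracted points are reduced to a few hundred
   key points by greedy sphere absorption; spheres are finer where the
   directionality degree $l(v) = \lambda_2/(\lambda_0+\lambda_1+\lambda_2)$
   of the local covariance drops below 0.9, i.e. where branch directions
   mix. Each key point also carries the principal direction of its absorbed
   set as a local curve tangent.
4. **Topology.** Key points are joined by degree-capped 3-nearest-neighbor
   admission; edge proposals misaligned with the local tangents of *both*
   endpoints are rejected first (two near-parallel organs threading past
   each other otherwise acquire a bridge that loop breaking cannot always
   remove). Remaining closed loops are broken by deleting, per cycle, the
   edge with the largest combined weight
   $W = W_s/\max W_s + W_c/\max W_c$, where $W_s$ sums the endpoints'
   distances to the cycle's total-least-squares plane and $W_c$ sums the
   edge's turning angles against its cyclic neighbors. The tree is split
   into a stem and leaves.
5. **Calibration.** Stem sections between leaf attachments are straightened
   by total-least-squares line fits; the base is extended down to the lower
   end of the near-axis cloud. Each leaf polyline is re-centered by cutting
   planes: every node is replaced by the centroid of the original leaf
   points in a slab perpendicular to the local tangent, the tip is recovered
   by marching the plane forward until it runs out of points, and the
   attachment (growth point) is reconstructed by extending a robust
   quadratic through the first measured nodes back to the stem line.

## What the traits mean

For each leaf, ordered from the lowest attachment up: *leaf length* (arc
length of the polyline from growth point to tip), *inclination angle*
(angle between the base tangent and the stem axis), *top length* (arc
length from the base to the leaf's highest point, with the flat apex
located by a local quadratic in height over arc length), *azimuth*
(counter-clockwise horizontal angle from the lowest leaf, which is 0 by
convention) and *growth height* (vertical distance from the attachment to
the stem base). Per plant, *plant height* is the vertical distance from the
highest skeleton node of any organ to the base. Coordinates are meters, z
up; loaders can remap axes.

## Segmenting stem and leaves

Two design questions are genuinely open once the tree exists, and the
package resolves them with maize architecture rather than local greedy
rules:

* **The stem** is the tree path from the lowest endpoint that maximizes the
  cumulative vertical rise penalized by horizontal wander,
  $\sum_e (\Delta z_e - \lVert \Delta xy_e \rVert)$. A maize stem is
  near-vertical everywhere, while a detour into a leaf trades little rise
  for a large horizontal excursion, so the criterion tolerates individual
  junction nodes displaced sideways by sampling. Above the last
  organ-bearing junction the path is trimmed where it deviates laterally
  from the local stem line — an erect uppermost leaf otherwise continues
  the "stem" seamlessly.
* **Stem gaps** are repaired before segmentation: degree-capped
  nearest-neighbor admission can exhaust a stem node's budget on shorter
  redundant links, leaving a vertical gap whose only bypass runs through a
  leaf. If the traced stem reaches less than 70% of the node cloud's
  vertical extent, the stem tip is bridged to the nearest node above it in
  a narrow vertical corridor and loop breaking removes the detour.
* **Leaves** are the off-stem subtrees, one leaf per subtree (maize leaves
  do not branch; sub-branching inside a subtree is a sampling artifact
  unless it is long enough to be a second leaf whose junction fell above
  the last clean stem node). The polyline is the longest path from the stem
  into the subtree; all subtree points participate in calibration.
  Same-azimuth fragments attached within 8 cm are merged before
  calibration.

## Reconstructing the leaf base

Contraction glues each leaf's sheath region onto the stem: roughly the
first decimeter of every vein is unobservable in the contracted cloud, and
the tree's branching node sits above and outboard of the true attachment.
Since calibrated leaf nodes are slab centroids of a near-symmetric ribbon —
they sit on the vein to within millimeters — and a smooth vein is locally
quadratic, the package fits an arc-length-parameterized quadratic through
the first few off-stem nodes and extends it backward to the local
total-least-squares stem line. Numerical choices that matter here:

* at most six fit nodes, so arc length stays a faithful quadratic
  parameter; the node adjacent to the junction is used only if it lies
  within 15 mm of the curve through the others (it is frequently an
  absorbed-blob remnant), and a node whose residual stands far above the
  rest is dropped once;
* the attachment is taken where the backward curve first comes within 3 cm
  of the stem line (the distance minimum is shallow for erect leaves),
  continued to the line along the local tangent;
* a one-sided geometric bound protects against under-rotated
  extrapolations: a vein bends only away from the stem, so the secant from
  the attachment to the first measured node is steeper than the local
  tangent there, which caps how high the attachment can sit;
* the polyline base is rebuilt from the attachment along the vein tangent
  evaluated a quarter of the hidden span outside the attachment — the
  constant-curvature quadratic otherwise over-rotates, because a real vein
  straightens toward the sheath;
* attachments are never moved more than 0.35 m, nor more than 0.2 m below
  the branching node.

## The synthetic generator

`make_plant()` builds plants with exact analytic ground truth: a slightly
leaning stem cylinder (radius 1.2 cm) and 5–15 leaves whose veins are
planar quadratic Bezier arcs that rise from the sheath, arch over a highest
point and droop toward the tip, with ribbon-shaped blades tapering to zero
width at both ends. Defaults emulate the study conditions the package is
validated under: heights 1.1–2.4 m, leaf counts scaling with height,
alternate (180 degrees plus or minus 10) phyllotaxy, insertion angles
58 - 30 f degrees at height fraction f (floored at 22 degrees: fully
unfolded leaves — a still-furled whorl is a known failure regime and is
deliberately excluded), insertions spanning 13–92% of stem height (the
peduncle region is leafless, and the top leaf apex, not the stem tip, is
the plant's highest point in a pre-tassel canopy), 4 mm isotropic Gaussian
sensor noise, a brown pot frustum and 1% outlier clutter in "realistic"
mode. Pot colors are a single base RGB under varying illumination
(brightness scaling 0.9–1.1), which is what a uniformly colored plastic pot
actually exhibits and what the brightness-ratio-times-chroma-angle color
difference is designed to cancel.

What the generator does **not** emulate: occlusion and view-dependent
density, tassels and ears, leaf blade twist and undulation, wind
deformation, registration artifacts between scan stations, and furled upper
leaves. Passing tests therefore demonstrate the algorithmic pipeline under
clean geometry with known truth, not performance on raw field scans.

The color-difference metric has two deliberate blind spots that follow from
its definition and are documented rather than patched: equal-brightness
colors always compare as identical (the ratio term vanishes), and gray
colors match everything (the chroma angle is taken as 0). Pot color samples
must therefore be chromatic, and gray clutter will be removed with the pot
— harmless, since it is clutter either way.

## Validation protocol and problem sizes

The package's acceptance surface is a seeded six-plant "realistic" study at
10,000 points per plant (`run_study(6, seed = 1, "realistic")`, 69 leaves),
chosen to mirror a six-plant, 71-leaf field evaluation protocol while
keeping a full run under a minute on one CPU. Leaves are matched to ground
truth in growth-height order by monotone sequence alignment (pairing cost:
attachment-height difference plus scaled azimuth disagreement, with a
0.12 m penalty for skipping a row on either side). Plain rank pairing would
let a single missed or spurious leaf shift every rank above it — and a
centimeter-scale attachment inversion would turn two correctly recovered
opposite leaves into a 180-degree azimuth error pair — neither of which
matching by physical identity, as a digitized reference allows, would ever
produce. Unmatched leaves reduce the reported n. Per trait,
the normalized RMSE (percent of the reference mean) and the squared Pearson
correlation are reported; plant height counts once per plant.

Typical results at these conditions: leaf length about 2%, inclination
5–8%, top length about 2%, azimuth below 0.5%, growth height about 1%, and
plant height below 0.2% NRMSE. All six stay within the accuracy envelope
reported for skeleton-derived maize traits validated against 3D-digitizer
references (5.27, 8.37, 5.12, 4.42, 1.53 and 0.83% respectively).

## Known limitations

* **Inclination dispersion.** The R-squared of the inclination angle is
  0.84–0.93 across study seeds, below the 0.93 of the other traits. With
  exact analytic truth the inclination spread of a fully unfolded canopy is
  only about 8 degrees s.d., so the 2–3 degree noise floor of the
  base-tangent reconstruction — set by the unobservable sheath region —
  costs correlation directly. A digitized reference skeleton, whose sparse
  clicked points define the base tangent the same way the method does,
  correlates with the method more favorably than an analytic truth can.
  Usually a single top-whorl leaf per study decides the gap.
* **Top whorl.** Where an erect uppermost leaf meets the stem tip,
  contraction can merge the two into one curve. The stem trim, subtree
  splitting and fragment merging recover the usual cases, but the top
  leaf's attachment and base angle remain the least reliable outputs, and
  severely furled whorls are out of scope.
* **Junction detection by directionality is weak after contraction** at
  realistic densities: sheaths merge into the stem, so neighborhoods near
  junctions look collinear and few points fall under the 0.9 threshold.
  The pipeline therefore does not rely on it alone; the verticality-optimal
  stem path, tangent-coherent edge admission and growth-point
  reconstruction carry the segmentation.
* **Tassels and ears** are not modeled and would not be skeletonized
  correctly; plants after tassel emergence should be cropped below the
  tassel first.
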