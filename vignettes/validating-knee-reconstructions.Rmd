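---
title: "Validating X-ray-based 3D knee reconstructions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating X-ray-based 3D knee reconstructions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Two-dimensional-to-three-dimensional reconstruction methods promise
CT-free preoperative planning for total knee arthroplasty (TKA): a pair of
calibrated plain-film X-rays is turned into a patient-specific 3D bone
surface. Before such a reconstruction can drive implant sizing or robotic
cut guidance, its geometric fidelity has to be quantified against a CT
ground truth — globally over the whole bone, locally at the bony landmarks
surgeons actually use, along the simulated resection cuts, and in the
anatomical axes that set component rotation.

`kneeval` implements that validation pipeline. It takes a predicted bone
surface (STL) and a ground-truth segmentation (NIfTI/NRRD mask or STL),
rigidly registers them, and reports:

* **global RMSE** — root mean square of the distances from each prediction
  vertex to its closest ground-truth vertex,
* **landmark-region RMSE** — the same measure restricted to consensus
  regions built from repeated observer annotations of eight bony landmarks
  (five femoral, three tibial),
* **cut-contour RMSE** — the discrepancy between the cross-section
  contours of both models under a simulated distal femoral or proximal
  tibial resection plane,
* **axis angle statistics** — angular deviations of the trans-epicondylar
  axis (TEA), posterior condylar axis (PCA) and medial–lateral transverse
  axis (MLTA) projected into the cut planes, compared between modalities
  and against an inter/intra-observer baseline.

Because patient imaging cannot ship with the package, a synthetic-data
module generates stylized femur/tibia meshes with exact landmark truth and
a controllable error structure; every stage of the pipeline is tested by
parameter recovery on those models.

## Surface error model

All surface errors are vertex-to-vertex: the distance for prediction
vertex $\hat y_i$ is $\min_j \lVert \hat y_i - y_j \rVert$ over
ground-truth vertices $y_j$, and

$$\mathrm{RMSE} = \sqrt{\tfrac 1 N \sum_{i=1}^N d_i^2},$$

with $N$ counted on the prediction side. This is deliberately *not* a
point-to-surface distance: the vertex-to-vertex definition is the one the
validation protocol specifies, it is symmetric in implementation (both
directions are computable; `pred_to_gt` is the reported default), and on
meshes with sub-millimetre edge lengths the difference is small. A
point-to-surface helper (`point_to_mesh_distance()`) exists for geometric
checks but is not the reported metric. RMSE is reported at full precision
and only rounded (2 decimals) for display; cohort summaries use the sample
(n−1) standard deviation, which is the convention that reproduces the
published per-patient table's summary row exactly.

## Registration

`icp_register()` is point-to-point ICP: exact nearest-neighbour
correspondences (kd-tree, rejection radius `max_correspondence` = 10 mm by
default), a closed-form least-squares rigid update (SVD/Kabsch), iterated
until the mean closest-point distance improves by less than `tolerance`
(1e-6 mm) or 100 iterations. Initialization aligns centroids and principal
axes; the four axis-sign combinations that keep a proper rotation are
scored by mean closest-point distance on a deterministic subsample and the
best is kept, which makes convergence robust to large misalignments of
elongated bones. The point-to-point metric matches the vertex-to-vertex
error definition; a linearized point-to-plane step and correspondence
trimming are available as options but are off by default, since the
validation protocol names only the basic algorithm.

## Mask-to-mesh conversion

`mask_to_mesh()` extracts the 0.5 isosurface of the binarized mask with a
marching-tetrahedra scheme (each grid cube split into six tetrahedra
around a fixed diagonal; neighbouring cubes agree on face diagonals, so
the surface is watertight; vertices are welded on global edge keys, so the
output is deterministic). Marching tetrahedra was chosen over table-driven
256-case marching cubes because it needs no case tables, is easy to verify
and yields the same class of surface; the extraction variant is
configurable territory, not part of the scientific contract.

One numerical choice matters here. Extracting an isosurface directly from
a *binary* occupancy field carries a staircase bias: on a 20-voxel-radius
binary sphere the extracted area overestimates the analytic value by
several percent (about +8.5% for a standard marching-cubes implementation,
more for marching tetrahedra). `mask_to_mesh()` therefore pre-filters the
binary field with a small Gaussian (`smooth_sigma` = 1 voxel) before
extraction; on the same sphere this brings area within 0.5% and volume
within 1.5% of the analytic values. Setting `smooth_sigma = 0` recovers
the raw binary isosurface. Masks so thin that the filter erases them
(single-voxel structures) automatically fall back to the raw isosurface
with a warning.

## Landmark regions

Observers annotate each landmark as a single 3D point, twice per observer
(3 observers × 2 presentations = 6 points per landmark per model).
`build_region()` fits a disc of predefined radius to those points:

* **outlier rule** — iteratively discard the point farthest from the
  centroid of the others while that distance exceeds
  `max(2 mm, 2 × median pairwise distance)`, never dropping below half the
  annotations (minimum 3). The protocol prescribes "discarding outliers"
  without a criterion; this rule is deterministic and scale-aware, and it
  is stated here as a package assumption.
* **radius** — the protocol's "predefined radius" value is unpublished;
  the default is 5 mm (configurable per call), comparable to the feature
  scale of the landmarks on an adult knee.
* **membership** — mesh vertices within the radius of the snapped centre,
  Euclidean by default (adequate at 5 mm scale on locally convex regions);
  geodesic membership along mesh edges is available via `igraph`.

The region is built on the prediction side and compared to the
ground-truth mesh (`local_rmse()`), mirroring the direction of the global
metric; which side the original study used is not stated, so the choice is
explicit and configurable by constructing the region on either mesh.

## Cut simulation

The femoral anatomical axis is fitted by slicing the shaft (25–75% of the
longitudinal extent by default) at 2 mm intervals perpendicular to the
principal axis and least-squares fitting a line through the section
centroids. The estimated mechanical axis rotates the anatomical axis by
the valgus angle (default 5°) about the anteroposterior direction
*orthogonalized against the axis*, through the distal axis point — the
orthogonalization makes the anatomical-to-mechanical angle equal the
requested angle exactly rather than approximately. The rotation sign moves
the proximal end medially (toward the femoral head), side-aware; the
varus/valgus sign convention is not stated by the protocol and is
configurable.

The distal femoral cut plane is perpendicular to the mechanical axis at a
9 mm offset from the most distal point of the medial condyle, which the
package operationalizes as the lowest vertex within the medial half and
distal quarter of the bounding extent. The proximal tibial cut plane uses
the tibial anatomical axis tilted posteriorly by the tibial slope about
the (orthogonalized) medial–lateral direction, at a 9 mm offset from the
plateau centre — the centroid of the most proximal 5 mm band of vertices,
which is robust to single-vertex noise. The slope default is 3° posterior:
the protocol says only "a tibial slope", so the value is a package
default in the common surgical range, flagged as such.

Cut contours are exact triangle–plane sections: segment endpoints are
keyed by the mesh edge they lie on, so chaining into closed loops is exact
and deterministic. Loops are projected into the plane's deterministic
(u, v) basis, oriented counter-clockwise, sorted by enclosed area (the
largest loop is compared by default; osteophyte-like side loops are
reported but not compared), and resampled at uniform arc length — 0.1 mm
by default, the protocol's contour rendering resolution, read here as
arc-length resampling. Resampling starts at the loop point with minimal u
(ties by minimal v) purely for regression-test determinism. Contour RMSE
then mirrors the surface definition: nearest resampled point of the other
contour, RMS over the prediction contour. Both models are sectioned with
the *same* plane, derived from the ground-truth model, so the contour
comparison isolates surface error rather than plane-construction error.

## Axis statistics

TEA, PCA and MLTA are lines through annotated landmark pairs, projected
onto the relevant cut plane (TEA/PCA onto the femoral plane, MLTA onto the
tibial plane). Angles are undirected line angles,
$\arccos |d_a \cdot d_b| \in [0°, 90°]$, so annotation order and direction
flips cannot create 180° artifacts. For each bone and axis:

* **baseline** — all $\binom{6}{2} = 15$ pairs of ground-truth
  annotations; mean and SD of the 15 angles quantify human-level
  annotation variation (intra- and inter-observer pooled, as the protocol
  pools them);
* **cross-modality** — all $6 \times 6 = 36$ prediction–ground-truth
  pairs.

Study-level reporting pools the raw pairwise angles across bones before
taking mean/SD (the simplest reading of the protocol's study-level
numbers); pooling per-bone means instead is available via
`study_axis_report(..., pooling = "bone_means")`.

## The synthetic generator

`generate_bone()` builds deliberately stylized bones as implicit-surface
unions of analytic primitives — a capsule shaft, two ellipsoidal condyles
(femur) or plateau lobes (tibia), a spherical tuberosity, a flattened
anterior cortex facet — sampled on a grid at the requested mesh density
and isosurfaced. Stylization is the point: every landmark (the eight
region landmarks plus the epicondylar TEA endpoints) has an exact analytic
coordinate, so region centres, axes and cut geometry can be checked
against known truth. A seeded ±3% size jitter emulates anatomic variation
across a cohort.

`perturb_bone()` emulates the reconstruction under test: a smooth random
offset field (Gaussian radial-basis expansion, correlation length 20 mm by
default, rescaled to the requested RMS exactly) displaces vertices along
outward normals, followed by a rigid misalignment. The perturbed mesh
keeps the ground-truth topology, so the injected per-vertex error is known
exactly and the pipeline's measured RMSE can be compared to it. Cohort
defaults draw per-patient offset RMS from normal distributions with mean
0.93 / SD 0.25 mm (femur) and 0.88 / 0.14 mm (tibia) — the error scale
published for X-ray-based knee reconstruction against CT — truncated at
0.3 mm; rigid misalignments are small (≈1° / 1 mm), matching models that
arrive near-aligned.

`simulate_annotations()` gives each observer a fixed 3D bias
(SD 1.5 mm/component) plus per-repeat noise (SD 1 mm/component) and snaps
each point to the nearest mesh vertex. The magnitudes sit in the range
reported for landmark annotation on knee CT (intra-observer ≈1 mm,
inter-observer from a few tenths to a few mm).

**What the generator does not emulate.** The bones are smooth analytic
unions: no cortical texture, osteophytes, or segmentation noise, and no
X-ray image formation — the module validates the *measurement pipeline*,
not any reconstruction algorithm. Two behaviours of the annotation model
deserve note when interpreting synthetic axis statistics. First, because
points snap to the surface, the noise component along the local surface
normal is suppressed; at the posterior condyles the in-plane direction of
the PCA is nearly normal to the surface, so synthetic PCA baselines are
tighter than TEA/MLTA baselines — real observers on real (less regular)
surfaces show no such collapse. Second, the per-observer bias translates
both endpoints of an axis by the same vector and therefore barely rotates
it; baseline angle spread is driven by the repeat noise, as in the real
protocol where a surgeon's systematic preference moves both epicondyle
picks together. Passing recovery tests on synthetic data therefore
demonstrates correctness of the computations, not clinical performance of
any reconstruction method.

## Numerical choices and degenerate inputs

* Patient frame: right-handed, +x left→right, +y posterior→anterior,
  +z distal→proximal, all mm. Left knees are mirrored into the right-knee
  convention on ingest (recorded on the `bone_model`), which unifies the
  valgus rotation sign and medial/lateral labels.
* Plane bases: u is the fixed reference (+z, falling back to +y near
  vertical normals) orthogonalized against the normal; v completes the
  right-handed triad. Identical inputs give bitwise-identical bases.
* Isosurface level 0.5 on binarized masks; zero-padding keeps surfaces
  closed at grid borders.
* STL: binary by default, ASCII optional; vertices welded
  deterministically in first-occurrence order; truncated binary files are
  rejected with the expected byte count, never silently shortened.
* Empty masks, empty regions, planes that miss the mesh, axes parallel to
  a projection plane, and annotation sets with no consensus all raise
  errors rather than returning degenerate values.
* One master seed drives every stochastic stage; per-stage child seeds are
  derived deterministically (and kept below 2^31) and recorded in the
  cohort manifest.

## Problem sizes used by the test-suite

Unit and acceptance tests run the generator at 2–2.5 mm mesh density
(roughly 10–20k vertices per bone, the scale of the clinical meshes),
registration recovery on ~12k vertices, offset recovery at
{0.45, 0.9, 1.8} mm RMS, Monte-Carlo oracles at 10^5 draws, and a 4-patient
end-to-end cohort in the acceptance script. These sizes were chosen so the
whole suite exercises every stage at realistic vertex counts while staying
fast enough to run routinely.

## Known limitations

* Vertex-to-vertex distances slightly overestimate true surface distance
  on coarse meshes; results are comparable between models meshed at
  similar density, which is the validation setting.
* The anatomical-axis fit assumes the mesh spans a usable shaft segment;
  very short fragments are rejected (fewer than 5 usable slices).
* Geodesic region membership uses edge-graph distances, an upper bound on
  true geodesic distance.
* The stylized generator cannot certify performance on pathological
  anatomy (severe osteophytes, bone loss); it certifies the measurement
  code.
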