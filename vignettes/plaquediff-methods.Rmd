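---
title: "Measuring longitudinal coronary plaque thickness change from contour stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring longitudinal coronary plaque thickness change from contour stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquediff)
```

## The measurement problem

Coronary plaque develops over years. Two CCTA acquisitions of the same
patient, segmented into per-artery stacks of paired lumen and
vessel-wall cross-sectional contours, contain everything needed to
quantify that development — except a correspondence: the scans sit in
different scanner coordinate frames, the contour stacks have different
point counts, and nothing links a position on the baseline wall to "the
same place" at follow-up. `plaquediff` computes, for every point of the
arterial surface, the signed change in plaque thickness

$$\mathrm{DIF}(v) \;=\; \mathrm{Thic}_{FU}(v) - \mathrm{Thic}_{BL}(v),$$

where thickness at a surface point is the Euclidean distance from the
lumen surface to the corresponding vessel-wall surface point, and
positive values denote plaque progression. (Both sign conventions
appear in the literature; this package fixes positive = progression,
consistent with classifying $\mathrm{DIF} > 0.5$ mm as an increase.)

The central design idea is that correspondence is *constructed, never
searched*: all four surfaces (baseline/follow-up × lumen/wall) of a
branch are refined from one coarse mesh, so equal vertex ancestry
identifies corresponding points by construction.

## Surface model

**Coarse mesh.** Each branch centerline carries one hexagonal ring (6
vertices) per resampled centerline point, oriented in the plane normal
to the local tangent. Ring azimuth is propagated with
rotation-minimizing frames (double-reflection parallel transport), so
consecutive rings do not twist against each other — important because
ring vertices become material identities. The initial ring circumradius
is half the branch's minimum lumen radius, guaranteeing the tube starts
strictly inside the lumen. Both tube ends are closed with a cap vertex,
which keeps the mesh closed so subdivision needs no boundary rules.

**Subdivision.** Loop (triangle) subdivision is applied, 2 levels by
default: each level quadruples the face count, and two levels give ~24
circumferential vertices, comparable to measuring thickness every 15
degrees around the lumen. Every vertex receives a stable ancestry id
derived from its coarse-mesh parents (ring/position for original
vertices, the sorted parent-id pair for edge vertices), plus a
fractional *ring coordinate* (axial position in ring units) and a cap
flag. Two surfaces refined from topologically identical coarse meshes
have identical ancestry id sets regardless of geometry.

**Fitting.** The surface grows toward the target contours iteratively.
Per iteration, for every tube vertex:

1. its axial station is the centerline arclength at its ring
   coordinate (fixed over the fit — vertices move essentially radially,
   so re-deriving the station by nearest-point search each iteration
   adds cost without changing the result on tubular geometry);
2. the target contour is interpolated at that station from the two
   bracketing contours, represented as radius-per-azimuth tables in
   rotation-minimizing frames (cross-sections are assumed star-shaped
   about the contour center, which holds for vascular lumina);
3. the force is the signed distance from the vertex to that interpolated
   contour along the in-plane projection of the vertex normal, and the
   vertex moves by `step` (default 0.5) times the force along that same
   in-plane direction, plus `smooth_weight` (default 0.2) times an
   umbrella-Laplacian smoothing term.

Iteration stops when the largest force magnitude falls below `force_tol`
(0.02 mm) or at `max_iter` (80). The wall fit starts from the fitted
lumen surface and simply grows outward (or stays, where wall and lumen
contours coincide — the zero-thickness convention for plaque-free
segments is fully supported).

Three numerical choices deserve justification:

* *In-plane force direction.* The target contour is planar, so the
  measured distance lives in the contour plane. Moving the vertex along
  its full 3D normal instead lets end-ring vertices — whose normals tilt
  axially — slide along the vessel without ever reducing their in-plane
  error; measuring and moving in-plane removes millimetre-scale
  artifacts at branch ends.
* *Attenuated normal smoothing.* The umbrella Laplacian on a
  discretised tube of radius $r$ with circumferential angle $\theta$ has
  an inward radial bias of order $r(1-\cos\theta)$ (~0.07 mm at wall
  radius at 15 degrees). At equilibrium this bias balances the fitting
  force at a standing residual comparable to `force_tol`, stalling
  convergence and shrinking the surface. The smoothing term therefore
  retains only a fraction `smooth_normal` (default 0.25) of its
  surface-normal component; tangential regularisation — which is what
  keeps the vertex distribution even — is untouched.
* *Cap handling.* Cap-descended vertices carry no fitting force (they
  face no contour) and relax each iteration to the average of their
  neighbours; tube vertices smooth over tube neighbours only. Without
  this split, the force-free cap region contracts toward the centerline
  and drags the end rings with it. Cap vertices are excluded from all
  thickness statistics.

## Registration and correspondence transfer

Baseline/follow-up correspondence starts from the centerlines: one
point per contour (the area centroid of the lumen polygon in its own
plane — for tubular cross-sections this matches medial-axis centerlines
without requiring a surface-based extraction), cubic-spline interpolated
(natural boundary conditions) over cumulative chord length and resampled
every 0.5 mm.

The pooled follow-up centerline cloud $X$ is registered onto the
baseline cloud $Y$ with **rigid coherent point drift**: $Y$ is modelled
as data from an isotropic Gaussian mixture centred on the transformed
$X$ plus a uniform outlier component of weight $w$ (default 0.1, which
absorbs branch segments present in only one acquisition). The EM
iteration solves rotation by SVD of the weighted cross-covariance with
determinant correction, translation from weighted means, and a shared
variance update; scale is fixed at 1 by default (same patient, mm
units) and can be enabled. A rigid model is deliberate: it preserves
point spacing, so genuine local plaque-driven centerline shifts survive
as residuals instead of being absorbed into the deformation.

CPD's soft assignment is many-to-one, so it is resolved to a one-to-one
map: every follow-up point proposes its maximum-posterior baseline
point; each contested baseline point keeps the Euclidean-closest
transformed candidate (ties break to the lower index for determinism).
Each kept pair stores the residual translation $T(x_i) = y_k - x_i'$.
The follow-up coarse mesh is then mapped into baseline space ring by
ring — global rigid transform plus the ring's $T$ vector, interpolated
linearly along the branch for unmatched rings, since every baseline ring
needs a transform donor — and used to fit the baseline surfaces. Ring
stations are re-derived in baseline arclength terms by projecting mapped
ring centers onto the baseline centerline.

## Classification, statistics and outputs

Per-vertex differences are classified with a threshold (default 0.5 mm):
the closed interval $[-0.5, 0.5]$ is *no change*, beyond it *increase* /
*decrease*; boundary values count as no change. Regional statistics are
unweighted per-vertex summaries over an axial window of a branch,
excluding cap vertices. Surfaces export as binary little-endian PLY or
legacy ASCII VTK with the field as a per-vertex scalar plus RGB colours
(thresholded mode: red = increase, yellow = decrease, gray = no change).

## The synthetic validation suite

The generator emulates what the published validation did on a clinical
host scan, without any scan: three branches (RCA 60 mm, LAD 55 mm, LCx
45 mm) with planar-arc centerlines (radii of curvature 90–110 mm) plus a
gentle out-of-plane bend, circular cross-sections tapering linearly
(1.9→1.3 mm lumen radius proximal→distal on the RCA), a constant 0.6 mm
concentric wall offset, contours every 0.5 mm with 48 points each.
The 48-point sampling (7.5 degrees) keeps the polygon's radial ripple
$r(1-\cos(\pi/48))$ well under the 0.02 mm force tolerance; coarser
24-point contours leave a ripple that the smoother cannot follow. The
0.6 mm wall offset accommodates the largest upward lumen edit (+0.5 mm)
while keeping wall outside lumen everywhere.

Plaque edits move contour points radially in-plane: `dR_lumen` /
`dR_wall` over an axial window of length $L$, boxcar profile with one
half-amplitude transition contour at each window end (emulating abrupt
manual contour edits while keeping the ground-truth region
well-defined), creating a known thickness change `dR_wall − dR_lumen`.
Edits are concentric by default; an angular extent with cosine taper is
available for eccentric plaques. The follow-up then receives one global
rigid transform (rotation 5–15 degrees, translation up to 10 mm) and
independent zero-mean Gaussian radial jitter (sd 0.05 mm) per contour
point, emulating delineation noise. The ten standard cases cover plaque
lengths 2/4/6 mm, lumen changes −1.0 to +0.5 mm, a wall-only increase
(positive remodeling), plaques at three axial positions and on all three
branches, and a simultaneous lumen+wall increase whose true thickness
change is zero (the bias control).

What passing on these data does *not* show: real contours are
non-circular and locally eccentric, segmentation error is spatially
correlated rather than independent radial jitter, cardiac-phase
deformation is not rigid, and branch topology can differ between
acquisitions beyond missing distal segments. The suite validates the
correspondence-and-differencing machinery, not the upstream
segmentation.

Statistics are evaluated over the full-amplitude interior of each edited
window (transition contours and caps excluded). At the defaults, each
case's mean calculated difference lands within 0.05 mm of its created
value, and the standard deviation of those deviations across the ten
cases is ~0.02 mm; the published experiment reports the same recovery
within ±0.1 mm, with per-case means slightly further below the created
values (e.g. 0.42 for a created 0.50), consistent with a more strongly
smoothed surface fit and with averaging that includes transition zones.

## Problem sizes and determinism

Default problem sizes were chosen as realistic for coronary trees: ~320
centerline points and ~31,000 surface vertices per tree — matching the
scale reported for clinical subdivision surfaces — with the full
ten-case suite completing in a few minutes on one CPU. Everything is
deterministic given the configuration: the generator seed drives poses
and jitter; the pipeline itself contains no randomness (CPD is
deterministic EM from a fixed initialisation; ties break by index).

## Known limitations

* Branches are modelled as independent tubes; bifurcations are not
  welded, and the markers/registration treat the tree as one point
  cloud.
* Star-shaped cross-sections are assumed when resampling contours by
  azimuth; grossly non-star-shaped (e.g. dissected) lumina would need a
  different target parameterisation.
* The fitted surface is the refined control mesh pushed onto the
  contours, not an exact Loop limit-surface evaluation.
* Vertex *positions* (not the fitted surface) depend on the initial
  frame azimuth: the rotation-minimizing frame seed uses a fixed
  reference axis, so fitting a rigidly rotated problem reproduces the
  rotated surface but with vertices parameterised at different azimuths
  unless the rotation fixes the reference axis.
* With contour noise, per-vertex differences inherit fit noise of
  ~0.05–0.09 mm sd; the 0.5 mm classification threshold is far above
  this floor, but single-vertex classifications near the threshold
  should not be over-read.
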