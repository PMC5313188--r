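---
title: "Measuring 3D acetabular orientation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring 3D acetabular orientation: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetabulometry)
```

This vignette documents the measurement model the package implements,
the parameters a user may reasonably want to touch, the synthetic
phantom that backs the validation and reliability machinery, and the
numerical decisions taken where several defensible options existed.

## The measurement model

The quantity of interest is the orientation of the acetabular axis — the
normal of the best-fit circle through the acetabular rim, oriented out
of the socket — expressed in an intrinsic pelvic frame rather than the
scanner frame, so that pelvic posture during acquisition drops out.

**Scanner frame convention.** All coordinates are in millimetres with
+X towards the subject's right, +Y anterior, +Z superior; the coronal,
sagittal, and axial planes are XZ, YZ, and XY. Mesh and volume
importers are expected to deliver data in this convention; one fixed
convention per package beats guessing per file.

**Anterior pelvic plane (APP).** The classical APP passes through the
two anterior superior iliac spines (ASIS) and the midpoint of the pubic
tubercles (PT). Manual picks of these landmarks are uncertain by
several millimetres, so the picks are refined: given the current plane
normal, the search replaces each landmark by the mesh vertex with
maximal projection along the normal (the most ventral point) within a
neighbourhood of the current landmark, then refits the plane through
the two refined ASISs and the refined PT midpoint; iteration stops when
the same four vertices are selected twice in a row. On a finite vertex
set this either converges or cycles; cycles are detected against the
visited-state history and resolved by returning the iterate whose own
selected vertices have the largest summed ventral projection, with a
warning. Ties in the extremal-vertex search are broken by the lowest
vertex index, making the refinement fully deterministic. The plane is
refit through exactly three points (the two ASIS vertices and the PT
vertex midpoint) each iteration — the literal geometric definition of
the APP — rather than by least squares over a larger set; the latter
would change what "the APP" means rather than estimate it better.

**Mid-sagittal plane (MSP).** Pelves are not exactly symmetric, and a
sagittal plane forced through midline landmarks inherits their pick
error. Instead the MSP is estimated as the mirror plane of the two
ASIS-region point clouds: all mesh vertices within a radius of each
refined ASIS are pooled, reflected across an initial candidate plane
(through the mid-ASIS point, normal along the ASIS line), and the
reflected cloud is registered back onto the original with a
point-to-point iterative closest point loop (nearest-neighbour
matching, SVD rigid update). The composition of the initial reflection
with the recovered rigid transform is an improper orthogonal map; its
eigenvector with eigenvalue closest to −1 is the mirror normal, and the
plane offset follows from the map's translation component. For a cloud
that is exactly mirror-symmetric this recovers the symmetry plane
exactly; for mildly asymmetric clouds it returns the least-squares
mirror plane of the region actually used.

**Frame assembly.** Y is the APP normal (anterior); Z is the unit
APP–MSP intersection direction pointing superiorly (away from the PT
midpoint); X = Y × Z. Because Z is constructed inside the APP, the
triad is orthonormal by construction and the MSP is re-expressed as the
plane through the mid-ASIS origin with normal X (the minimal rotation
that makes the triad exact). The transverse pelvic plane is the plane
through the origin with normal Z. Frames are rejected when the APP and
MSP normals are within 10° of parallel, where the intersection
direction becomes ill-conditioned.

**Posture.** Tilt is the signed angle of the anterior APP normal in the
sagittal projection (positive when the normal gains a superior
component), so a pure axial rotation of the pelvis yields zero tilt;
rotation and obliqueness are the unsigned acute angles between the MSP
and the sagittal plane and between the TPP and the axial plane. With
these conventions a pure rotation about the scanner X axis changes only
tilt (and tips Z by the same amount), and a pure axial rotation changes
only the rotation angle.

**Opening circle and axis.** The circle is fitted to the raw picked rim
points in three stages: best-fit plane (centroid plus
smallest-singular-value direction), algebraic least-squares circle in
the plane (the linear Kåsa system), then geometric refinement
minimizing the sum of squared true 3D point-to-circle distances
(BFGS, followed by a Nelder–Mead polish; the 3D distance of a point at
in-plane radial distance ρ and out-of-plane height h from a circle of
radius r is √((ρ − r)² + h²)). The plane-project-refine route is more
robust than launching a 6-parameter 3D optimization cold, and the
refinement stage makes the result a genuine 3D least-squares circle.
The closed cubic B-spline rim path (points ordered by angle about
their centroid in the fit plane, periodic interpolating spline in
chord-length parameter) is retained for visualization and diagnostics;
fitting to a dense resampling of the path instead of the raw picks
moves the axis by well under 0.1° on phantoms, so the raw-point fit is
the default and the spline never silently re-weights the data.

**Angle definitions.** With unit axis components (l, a, s) =
(outward-lateral, anterior, superior) after side normalization
(l ≥ 0):

* anatomic: AI = acos(−s), AA = atan2(a, l)
* radiographic: RA = asin(a), RI = atan2(l, −s)
* operative: OI = asin(l), OA = atan2(a, −s)

These imply sin RA = sin AA sin AI, tan RI = tan AI cos AA,
tan OA = tan AI sin AA, and sin OI = sin AI cos AA, which the test
suite verifies to 1e-12 together with an independent projection-based
oracle. Anteversion is signed, so retroverted sockets come out
negative rather than clamped; a purely lateral axis (inclination 90°,
anteversion 0°) makes operative anteversion a 0/0 case, which is
reported as 0 with a warning. The axis orientation rule (outward
lateral component positive; ties broken by positive anterior component)
makes left/right mirror symmetry exact: mirroring a pelvis across its
MSP and swapping side labels leaves all six angles unchanged.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `app_region_mm` | 10 | mm | radius of the extremal-vertex search; large enough to absorb ~5 mm pick error, small enough that the ASIS prominence is the only ventral extremum inside it |
| `msp_region_mm` | 25 | mm | ASIS cloud radius; a "larger area" of ilium stabilizes the mirror registration without pulling in structures far from the ASIS |
| ICP iterations / tolerance | 100 / 1e-6 | –, mm | point-to-point ICP with SVD updates; the tolerance is on the change in RMS residual |
| `circle_tol` | 1e-10 | – | relative convergence of the geometric circle refinement |
| smoothing `iterations`, `lambda`, `mu` | 10, 0.5, −0.53 | – | Taubin pass-band pair; the slightly larger negative step keeps the pass-band near zero shrinkage |
| `gap_mm` (voxel phantom) | 2 | mm | joint-space width; must be at least one voxel so the ball and socket stay disconnected |
| rater noise | 5 (landmarks), 1 (rim) | mm | plausible manual pick scatter; 5 mm exercises the APP refinement's convergence basin rather than staying trivially at the optimum |

The ICP source cloud is deterministically subsampled to at most 800
points (the target cloud is kept whole) to bound the cost of
brute-force nearest-neighbour matching; on phantom-sized ASIS clouds
this changes the recovered plane negligibly (the symmetric-phantom
recovery test bounds the total MSP error at 0.1° over a 50-pose
ensemble).

## The synthetic phantom

Ground truth for a measurement pipeline must be analytic, so the
standardized phantom is deliberately schematic rather than anatomic:
two iliac slabs carrying spherical ASIS prominences whose anterior
poles are exactly the nominal ASIS coordinates, a pubic bar with PT
prominences, hemispherical cup shells whose opening-circle normals
realize exactly the requested anatomic angles, and connecting struts
(superior ramus, ilium strut, cup strut) sized so that the whole solid
is one 26-connected component after voxelization while never
approaching the femoral-head ball or the rim circle. Landmark picks,
rim points (optionally skipping a 60° notch sector), all three planes,
the rim circles, and all six angles per side are known in closed form,
and any rigid pose can be applied on top.

What the phantom emulates: the geometry of the measurement problem —
landmark prominences with a unique ventral extremum, an exactly
mirror-symmetric ASIS region, rim points on a known circle, staircase
and partial-volume effects after voxelization, joint-space separation
between femoral head and socket. What it does not emulate: anatomic
shape variation, cortical/trabecular intensity structure, imaging
noise spectra, or genuinely asymmetric pelves. Passing the phantom
suite therefore demonstrates correctness of the geometry pipeline and
its noise propagation, not clinical segmentation performance; the
asymmetric-bump and rater-noise tests probe robustness only locally
around the symmetric ideal.

The 15-model validation suite varies the true anatomic anteversion over
5–35° and inclination over 40–65° on a deterministic grid (the
inclination grid phase-shuffled against the anteversion grid so the
suite covers the rectangle, not its diagonal), with the pelvis geometry
held fixed — orientation is what the pipeline measures, so orientation
is what the suite spans. Simulated populations draw per-subject
anatomic angles from truncated normal distributions with per-sex means
at the published cohort values and standard deviations set to
range/4 (the cohort tables print ranges, not SDs); bilateral
left-minus-right differences use the published bilateral means with
SD set to max/3. Simulated raters perturb landmark picks tangentially
on the surface (uniform direction, uniform distance up to the noise
magnitude, snapped back to a mesh vertex) and rim picks along the
socket sphere.

## Segmentation stage

The femoral head is removed by fitting a sphere to joint-surface points
(algebraic least-squares on the linearized normal equations, exact on
noiseless spheres) and blanking all voxels within radius plus a margin.
Region growing returns the maximal 26-connected component within an
intensity window containing the seed. Surfaces are extracted as the
0.5-level isosurface using a marching-tetrahedra traversal of the
Freudenthal 6-tetrahedron cube decomposition, which is
translation-invariant across the grid and therefore watertight on
solid masks; vertices interpolate the iso level along tetrahedron
edges (edge midpoints for binary masks) and triangle winding is
oriented away from the super-level set. Smoothing is the Taubin
shrink/inflate pair rather than plain Laplacian smoothing because the
enclosed-volume contract (< 0.1 % change at defaults) rules out the
systematic shrinkage of the latter.

## Reliability statistics

Ratings matrices pool the anteversion and inclination rows of one
angular definition (hips × measures by raters), matching how
per-definition reliability tables are reported; per-angle matrices can
be built by subsetting the trial table if the pooled layout is not
wanted. The ICC is the single-measure absolute-agreement coefficient
from the two-way ANOVA decomposition,
(MSR − MSE)/(MSR + (k−1)MSE + (k/n)(MSC − MSE)), with the McGraw–Wong
F-based 95 % confidence interval; the two-way random (interrater) and
two-way mixed (intrarater, raters fixed) models share this point
estimate and are distinguished by the recorded model tag. Matrices
with (near-)zero total variance — e.g. noise-free simulated raters —
are flagged as degenerate rather than returning 0/0. The point
estimate is verified against explicit sums-of-squares arithmetic in
the tests.

## Numerical choices and degenerate inputs

* Extremal-vertex ties: lowest vertex index wins (deterministic).
* Collinear APP points, coplanar sphere points, collinear rim points,
  near-parallel APP/MSP, empty masks, seeds outside the intensity
  window, non-manifold meshes handed to the smoother: all hard errors
  with specific messages, not silent fallbacks.
* The phantom generator enforces an open inclination interval (0°,
  90°); the degenerate fully-lateral axis is still covered analytically
  through the conversion functions.
* Mesh vertices are welded at 1e-6 mm; volume parity rays in the
  voxelization oracle are offset by distinct irrational sub-voxel
  amounts so they cannot hit vertices or grid-aligned edges exactly.
* Seeds: every stochastic helper takes an explicit integer seed;
  phantom generation itself is fully deterministic.

## Problem sizes used by the shipped tests

The test suite and the acceptance script choose sizes that keep the
full run to a few minutes while leaving the conclusions unchanged:
phantom meshes at 1 mm edge length (~100k vertices) for the validation
suite, pose-invariance, and reliability protocols, and 2 mm for
geometry-only property checks; 15 validation models; 16 phantoms × 3
raters for reliability; 300-replicate Monte-Carlo loops for the circle
fit; a 50-pose ensemble for MSP recovery; voxel phantoms at 1 mm
spacing. The published cohort itself (100 subjects of CT angiography)
is not redistributable and is out of scope: cohort-level tables are
reproduced only as report *formats* and simulated-population summary
utilities, never as values.

## Known limitations

* The MSP estimate assumes the ASIS regions are informative about the
  mirror plane; pelves with grossly asymmetric or dysplastic iliac
  wings violate this, as they do for any symmetry-based method.
* The rim points are user picks; automatic rim detection is explicitly
  out of scope.
* The segmentation stage assumes an intensity window separates bone
  from background after head removal (true for the phantom and for
  high-contrast CT; not for MR).
* DICOM ingestion and Hounsfield calibration are out of scope; volumes
  enter as NIfTI.
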