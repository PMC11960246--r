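---
title: "Methods: cartilage shape models, defect heat maps and local curvature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cartilage shape models, defect heat maps and local curvature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartmorph)
```

This vignette documents the models and procedures implemented in
`cartmorph`, the assumptions behind them, the numerical choices that were
genuinely open, and what the synthetic validation does and does not
demonstrate about real MRI-derived data.

## The analysis problem

Focal cartilage defects of the distal femur are treated increasingly with
small resurfacing implants. Designing a *generic* (non-patient-specific)
implant requires population statistics of (i) defect location on the
articular surface, (ii) defect footprint size and elongation, and (iii)
the local shape of the healthy surface at high-incidence sites, expressed
as signed anteroposterior (AP) and mediolateral (ML) radii of curvature.
All three are computed here from triangulated surface meshes (mm) of
reconstructed "native" cartilage and paired defect models.

The working anatomical frame is a left knee: +x medial, +y anterior,
+z proximal; the articulating surface faces distally. Right-knee models
are mirrored in the sagittal plane (x = 0) on load, with face winding
flipped so outward normals stay outward.

## Correspondence

Dense correspondence across k meshes is established against one reference
(a configurable index, by default a seeded random choice). Each target is
first rigidly aligned by ICP with nearest-vertex matching and the Kabsch
orthogonal Procrustes update; the mean closest-point residual is
non-increasing by construction, and principal-axis restarts (the four
proper sign combinations) guard against poor basins under large initial
misalignment, keeping the procedure deterministic.

The reference is then deformed onto the target with a locally affine,
stiffness-relaxed non-rigid ICP: each vertex carries a 3×4 affine
transform, neighbouring transforms are penalised for disagreeing through a
graph stiffness term weighted α, and α is relaxed over a schedule (default
8 log-spaced levels from 50 to 0.5, up to 10 inner iterations each,
stopping when mean vertex movement < 1e-4 mm). The sparse normal equations
are solved with the Matrix package. Matches are rejected (weight zero and
flagged) when vertex normals disagree by more than 60° or when the closest
target vertex lies on the target boundary — missing regions are flagged,
never extrapolated silently. These defaults are package choices; dense
anatomical correspondence methods differ mainly in regularisation
strength, and the planted-truth tests below measure the consequences
directly. When inputs already share one topology (every synthetic cohort),
`method = "shared_topology"` takes the known vertex correspondence as-is
and leaves pose removal to the alignment stage, which finds the global
Procrustes optimum per shape.

## Shape model

Generalised Procrustes alignment translates centroids to the origin and
iteratively rotates each shape onto the running mean until the mean moves
less than 1e-6 mm (at most 100 iterations). Scaling is *off* by default —
size is biologically informative here and is retained as shape variation;
each shape's centroid size is then preserved exactly. The mean shape is
defined up to a global rigid transform, so invariance tests compare means
after aligning them.

PCA of the aligned coordinates is computed by thin SVD of the centred
k × 3m data matrix (k ≪ 3m), which is the numerically stable route to the
eigendecomposition of the sample covariance; mode variances are the
squared singular values over (k − 1), and at most k − 1 modes exist.
Synthesis is the linear form S = S̄ + P b; projection is its adjoint, and
the two round-trip to 1e-8 on the model's span. Population sampling draws
b_i ~ N(0, λ_i) independently, truncated at ±3√λ_i by resampling (a
conventional guard against implausible extrapolation; configurable, and 0
degenerates to the mean shape).

Model quality follows the standard triple: compactness (cumulative
variance fraction), accuracy (RMS vertex distance of each training shape
to its m-mode reconstruction), and generalisation, computed by
leave-one-out retraining with the held-out shape re-aligned to the reduced
mean before projection. Leave-one-out is our protocol choice for
"instances not included in the training data"; with k ≈ 70 it is the
standard small-cohort estimator.

AP length is the distance from the most anterior vertex to the line
joining the most posterior vertices of the medial and lateral condyles;
ML width spans the most medial vertex of the medial condyle to the most
lateral of the lateral condyle. The visual check that a sampled population
covers the input's (AP, ML) scatter is operationalised as the fraction of
sampled points inside the input convex hull inflated by 5% (threshold
0.8); both numbers are design choices for an inherently graphical
comparison.

## Defect heat map

Native models are similarity-aligned (rotation, translation *and* scale)
to the mean shape — unlike SSM construction, so that defect footprints
from differently sized knees land on one common surface — and each
model's transform is applied verbatim to its paired defect model,
preserving congruence up to the common scale. The applied scale also
scales defect footprints; reports carry the scale so the distortion is
visible. A mean-shape vertex counts a defect when the unsigned
closest-point distance from the vertex to the defect's articulating
surface is at most τ. "Overlap" has no unique definition for open sheet
meshes where inside/outside is undefined; τ-proximity is robust and
order-invariant, and τ defaults to 1.0 mm, the coarsest voxel dimension of
typical knee MRI, so that "touching within scan resolution" counts.
Counts are monotone in τ and bounded by the number of defects. Regional
maps (medial/lateral condyle) mask by face labels; masked-out vertices
keep their counts but are flagged.

## Defect geometric characteristics

The defect's articulating faces (labelled, or all faces when unlabelled)
define the measurement set. The major axis is the exact maximum pairwise
distance between articulating vertices. The conventional minor axis — the
greatest extent perpendicular to the major axis — is ambiguous in 3D; we
define it as the diameter of the vertex set projected onto the plane
orthogonal to the major direction, which equals the maximum extent over
all perpendicular directions, reduces to the in-plane definition for
near-planar defects, and guarantees aspect ≥ 1 (a projection never
lengthens distances). A 1°-step angular scan serves as the independent
test oracle. Collinear vertex sets are flagged degenerate. A flag
(`all_points`) switches to every vertex of the defect model for
sensitivity analysis; articulating-only is the default since the
articulating footprint is the object of interest.

## Local radii of curvature

A least-squares circular cylinder is fitted to the posterior condylar
vertices: for a candidate axis direction the points are projected along
it and a circle is fitted (Pratt's algebraic fit, then geometric
Gauss–Newton), and the direction minimising the RMS of
(distance-to-axis − r) is found by Nelder–Mead over the unit sphere from
the three principal axes of the point covariance — deterministic by
construction. Near-spherical point sets (a least-squares sphere explains
the data essentially as well, making the axis azimuth indeterminate) and
near-planar sets (projected radius diverging) are flagged
ill-conditioned; on a sphere the fitted axis still passes near the centre,
so the measurement planes below remain meaningful and the sphere
consistency tests pass.

At a probe point, the AP plane has the cylinder axis as its normal; the
ML plane contains the probe and the whole axis (undefined, and an error,
for a probe on the axis). The region of interest is an ellipse in the
probe's tangent frame: major axis along the AP tangent (the intersection
of the AP plane with the tangent plane), sized by
`patch_dimensions(area, aspect)` = (2√(A·r/π), 2√(A/(π·r))). The printed
reference footprint is 2.70 cm² at ratio 1.70, i.e. 24.2 × 14.2 mm — note
that 24.2/14.2 = 1.70, so the package pairs these axes with ratio 1.70
throughout and takes (area, aspect) as explicit inputs rather than
silently reconciling other pairings. Faces are selected by centroid
membership, and the connected component containing the probe is kept;
tangent-frame membership (rather than geodesic discs) is exact for flat
patches and biased only at O((patch size / local radius)²), which the
sphere tests bound at ≤ 3% of area on a 100 mm sphere. Patches touching
the mesh boundary are flagged.

Each radius is a circle fit to the *exact mesh–plane section* of the
patch (triangle–plane crossing points), not to a projection of the whole
patch: projecting all patch points into a plane on a doubly curved
surface shrinks the apparent radius by ≈ E[d²]/2R (d the off-plane
distance), up to ~5% for the ML plane of the reference ellipse on a 20 mm
sphere — larger than the agreement the method is expected to deliver.
Section points lie on both the surface and the plane, so no projection
bias enters. `fit_circle_in_plane()` also accepts arbitrary point sets
with an optional off-plane slab filter for the same reason. The sign is
set by the side of the fitted centre relative to the outward surface
normal at the probe: bone side = convex = positive. Radii above 500 mm,
or ill-conditioned/collinear fits, are reported flat rather than as huge
signed numbers — the ML section of a cylinder is exactly straight and
must not alias into a finite radius.

Probe rows are placed on the section of the surface by the AP plane
through an anchor (the heat-map argmax in hotspot mode; user-supplied for
the trochlea, where surgical experience replaces sparse data), equally
spaced in arc length via the section's fitted circle. The default spacing
is half the reference-ellipse major axis; the pipeline halves it until
the row fits the available arc.

A finite patch measures an *average* curvature, not the point curvature:
on surfaces whose curvature varies across the patch the fitted radius
converges to the closed-form normal-section radius only as the patch
shrinks. The tests verify this small-patch limit explicitly (monotone
error decrease over 4, 2.7, 1 and 0.5 cm² on the synthetic trochlea) and
check tight agreement (≤ 5%) at moderate patch sizes on quadratic
saddles, where the variation is mild.

## Synthetic cohort generator

The generator is the package's source of ground truth, not an anatomical
atlas. The base surface is a parametric sweep F(u, v) =
((W/2)v, R sin u, g(u, v) − R cos u): sagittal circles of radius R
(condyle radius, default 40 mm) whose centres are lifted by a
mediolateral Gaussian ridge of height G (groove depth, default 6 mm,
rejected if ≥ R) gated anteriorly by a quintic smoothstep in u. The
posterior condyles are therefore *exactly* cylindrical (matching the
posterior cylinder-fit assumption) while the anterior centre carries a
trochlea-like groove: convex AP, concave ML, with all first and second
fundamental form quantities available in closed form
(`surface_truth_radii()`), verified in the tests against an independent
finite-difference oracle. With the defaults the trochlear probe has
AP = +40.0 mm and ML = −16.0 mm — the qualitative signature (+AP, −ML,
ML tighter) of a trochlear groove. Defaults for extent (AP arc 65 mm, ML
width 60 mm) are in the range of adult distal femoral cartilage; they are
stand-in values, chosen once.

Shape variation is planted through at most four fixed smooth displacement
fields (AP stretch, ML widening, groove-depth modulation, AP skew),
orthonormalised as 3m-vectors and projected orthogonal to the six
infinitesimal rigid motions so that Procrustes alignment cannot absorb
them — the planted PCA structure (mode directions and variances) is then
known exactly. Default amplitudes 2, 1, 0.5, 0.25 mm place millimetre-
scale population variation above a 0.1 mm vertex-noise floor, the order
of MRI segmentation uncertainty at 0.5 mm in-plane resolution. Each model
receives a random rigid pose (±15°, ±20 mm, emulating scanner placement)
and a coin flip (default 0.5) for right-sidedness, exported mirrored
("as-scanned") with a manifest side flag.

Defects are extruded elliptical patches of the native articulating
surface: centres drawn around a planted hotspot (parametric coordinate,
default on the posterior-distal medial condyle) with a configurable
spread in surface millimetres; areas log-normal around a 270 mm² median
(log-sd 0.63) and aspects 1 + log-normal around 1.6 (log-sd 0.6).
Log-normals are a modelling choice — strictly positive and right-skewed
as observed defect-size distributions are; no distributional form is
prescribed by the underlying clinical data. The log-sds were set once so
the quartiles fall near 1.7–4.0 cm² and 1.4–1.9. Because patch faces are
selected on a finite grid, realised patches are larger than the nominal
ellipse by about one edge ring: areas track the drawn truth to a few
percent, while measured axis lengths run ~1–2 mm long (and the measured
aspect correspondingly slightly low) at the default resolution — a
discretisation property the cohort-level tests accommodate within their
15% bands.

Analytic fixtures (sphere caps, cylinder patches, quadratic saddles,
planar ellipses, exact circle point sets) carry their closed forms as
truth records and serve as oracles for the fitting operations.

## What the synthetic validation does not show

The generator produces smooth, noise-controlled, topology-identical
surfaces with known correspondence. Passing its tests demonstrates the
correctness of the algorithms — recovery of planted modes, hotspots,
defect statistics and closed-form curvatures through the full chain — but
not robustness to real segmentation artefacts: missing or spurious
patches, topology differences, strongly anisotropic triangulations, or
anatomy outside the generator's shape family. The non-rigid
correspondence accuracy criterion (mean error ≤ 0.5 mm, the in-plane
voxel size) is evaluated on this smooth family; real cartilage with
defects may correspond less accurately near lesion rims.

## Problem sizes and reproducibility

All randomness flows from explicit integer seeds; cohort generation,
registration, sampling and the end-to-end pipeline are deterministic
byte-for-byte, which the acceptance tests check on serialised outputs.
The test suite works at the study's natural scale where the statistic
demands it (70-model cohorts for mode-ratio, hotspot and AP/ML-overlap
checks; 200-model sampled populations) on meshes of 660–1 700 vertices,
sizes at which every stage, including 20 replicate cohort builds, runs in
seconds on one CPU; registration unit tests use coarser grids. The
vignette and README examples use the defaults stated above.
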