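---
title: "Reprojecting 2D image annotations onto 3D terrain models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reprojecting 2D image annotations onto 3D terrain models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reproj3d)
```

## The model

A photogrammetric reconstruction provides, for every survey image $i$, a
calibrated pinhole camera: intrinsics (focal length $f$ in pixels, principal
point $(c_x, c_y)$, image size, radial distortion coefficients
$k_1, k_2, k_3$) and extrinsics (a world-to-camera rotation $R_i$ and camera
center $C_i$ in the local metric model frame), plus a triangle mesh of the
scene surface in the same frame. A 2D annotation is one or more pixel
positions on a named image.

Reprojection treats each annotated pixel as a line of sight. The pixel is
first rescaled from the annotated-image resolution to the calibrated
resolution (annotation platforms serve full-resolution images while
reconstructions usually run on downscaled copies), then undistorted to
normalized coordinates $(x_n, y_n)$, and cast as the ray
$C_i + t\, R_i^\top (x_n, y_n, 1)^\top$. The annotation's 3D position is the
first intersection ($\min t$) of that ray with the mesh. A ray that misses
the mesh — over an unreconstructed hole, or past the model border — makes the
annotation *discarded*: no position is invented for it. Positions are finally
georeferenced by interpreting the local frame as an east-north-up (ENU)
tangent frame at a WGS84 anchor.

Assumptions worth stating explicitly:

- **Single-ray positioning.** Each vertex uses only its own image's camera;
  no multi-view triangulation. The accuracy of the result is therefore the
  accuracy of the bundle-adjusted pose and of the mesh, not of any averaging.
- **Radial-only distortion** (Brown $k_1, k_2, k_3$), matching common SfM
  exports; inputs carrying tangential terms are rejected rather than
  silently misinterpreted.
- **The mesh is the surface.** If the mesh is locally wrong (Poisson
  artifacts, unmodelled relief), the reprojected position inherits that
  error — on rugged terrain a near-vertical surface can displace a hit by
  decimetres, which is the dominant real-world error mode.

## Conventions

Pixel $(0,0)$ is the top-left image corner, $u$ grows right, $v$ grows down,
coordinates are continuous with no half-pixel shift (BIIGLE convention). The
camera frame is $+x$ right, $+y$ down, $+z$ forward (OpenCV/OpenMVG), so
$x_c = R(X - C)$ with depth $z_c > 0$ in front. Rotations must be proper
(determinant $+1$, orthonormal to $10^{-6}$ on input, re-orthonormalized by
polar decomposition). Heights are ellipsoidal; underwater surveys simply have
negative heights, avoiding any geoid model dependency.

## Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `t_min` (ray caster) | 1e-6 | m | self-intersection guard, three orders below a typical 5 mm model resolution |
| undistortion tolerance | 1e-13 | normalized | keeps the inversion residual below 1e-9 px at typical focal lengths; damped fixed point, 100-iteration cap, error on failure |
| aspect-ratio tolerance | 0.5 % | — | annotated/calibrated size mismatch beyond this almost always means a wrong image pairing |
| `mode` (polygons) | `"strict"` | — | a polygon with any missing vertex is discarded; `"lenient"` keeps ≥ 3 surviving vertices as `partial` |
| `densify_n` (footprints) | 0 | points/edge | corner-only footprints match the common definition; densification is exposed because corners under-represent relief |
| visibility `epsilon` | 1e-3 | m | occlusion test tolerance when relocating a 3D feature in other images; one order below model resolution |
| duplicate `radius_m` | 0.05 | m | ~10x model resolution; genuine re-sightings of a feature reproject within millimetres, distinct organisms are rarely this close |
| `max_overlap_frac` | 0 | — | disjointness threshold on footprint overlap fractions |

## Numerical choices

- **Ray casting** is Möller–Trumbore over a median-split AABB BVH (leaf ≤ 4
  faces), in C++. Backfaces count as hits: photogrammetric meshes have
  inconsistent winding and culling would silently drop valid intersections.
  Triangles with area below $10^{-12}\,\mathrm{m}^2$ are flagged degenerate
  and excluded (Poisson meshes contain slivers); the mesh is not required to
  be watertight. Determinism: a parallel-plane cutoff of $10^{-14}$ on the
  Möller–Trumbore determinant, barycentric slack of $10^{-12}$ so shared
  edges are never missed, and a tie rule — when two hits are within
  $10^{-12}$ m along the ray, the lower face index wins regardless of
  traversal order.
- **Undistortion** inverts the radial model by damped fixed-point iteration
  from the distorted point, validated by re-distorting. The model is
  monotonic (hence invertible) over the image domain for the coefficient
  ranges the tests sweep ($|k_1| \le 0.2$, $|k_2|, |k_3| \le 0.05$).
- **Geodesy** uses the exact ENU→ECEF→geodetic chain on the WGS84 ellipsoid
  ($a = 6378137$ m, $1/f = 298.257223563$), with Bowring's closed form
  refined by fixed-point iteration to $10^{-14}$ rad. Round trips are
  sub-micrometre within 10 km of the anchor. The test suite checks this
  against an independent closed-form algebraic conversion (Vermeille's
  method) written separately from the package code.
- **Footprint overlap** projects footprints to the horizontal plane,
  convexifies them, and clips with Sutherland–Hodgman. Convexification can
  only overestimate overlap, which is the conservative direction when
  certifying disjointness. The independent check in the tests is a
  grid-counting (even-odd point-in-polygon) area estimate on the raw,
  unconvexified polygons.
- **Quantiles** (median, IQR = Q3 − Q1) use linear interpolation
  (`stats::quantile` type 7), stated in the report metadata; distances are
  3D Euclidean norms — on vertical structure the horizontal distance between
  stacked features is zero while the true separation is not, so 3D distance is
  the honest error measure.

## Design decisions that were genuinely open

- **Undistortion of annotation pixels** is applied whenever distortion
  coefficients are present in the camera file. Skipping it would bias rays
  by up to several pixels near image corners for typical $k_1$.
- **Strict polygon discard by default.** Discarding an annotation whose ray
  misses is unambiguous for points; for polygons one could also keep the
  surviving vertices. Strict all-or-nothing is the default because a
  partially-projected patch outline has a different (smaller) area than the
  annotated patch; lenient mode is an explicit opt-in and labels its output
  `partial`.
- **Local frame = ENU at a configured anchor.** SfM toolchains differ in
  what frame they export; an explicit anchor keeps the georeferencing
  assumption visible and testable. (A projected-CRS variant would slot in
  at the same interface; it is not implemented because no consumer in this
  codebase needs it.)
- **Greedy disjoint selection in acquisition order**, testing each candidate
  against already-accepted images by *its own* overlap fraction
  (intersection / candidate's area). This mirrors a one-pass survey
  workflow and is what the exhaustive reference solver (max independent set
  under the symmetric pair rule, ≤ 20 images) is compared against in tests.
  With the near-equal footprint areas of a fixed-altitude survey the
  asymmetric and symmetric rules coincide.
- **Duplicate percentage convention**: one representative kept per group,
  i.e. $100 \cdot \sum (\text{group size} - 1) / N$. Two coincident
  annotations are thus 50 % duplicated. The convention matters when quoting
  a single percentage and is therefore fixed and documented.
- **Camera–annotation matching is exact by filename**; a case-insensitive
  stem fallback exists behind a flag because silent fuzzy matching hides
  pairing bugs.

## The synthetic-survey generator

`generate_scene()` builds a fully specified survey so that every stage has a
ground truth: a height-field terrain (flat; sinusoidal with amplitude and
wavelength; or a seeded random field — white noise smoothed by a separable
Gaussian kernel and rescaled to a target amplitude, a controllable-roughness
stand-in for rugged vent terrain versus a flat sedimented terrace); nadir
cameras along a serpentine fixed-altitude trajectory; features sampled on
the mesh surface with one 2D point annotation per camera that sees them
(in bounds, in front, unoccluded); and optionally a drifting navigation
track.

Defaults are chosen once to resemble a small deep-sea photo survey:
altitude 5 m (surveys of this kind fly 3–6 m), one frame per metre along
track, 3 m line spacing (generous cross-track overlap), a 2000×1500 px
calibrated camera with $f = 1400$ px and mild barrel distortion
($k_1 = -0.05$), annotations made at 2× the calibrated resolution so the
rescaling path is always exercised, and a 0.25 m terrain grid.

The navigation-noise model is a deliberate caricature of hybrid navigation,
not a navigation simulator: per metre travelled the planar position offset
random-walks with step σ = `drift` (0.02 m/m in the mismatch experiments),
and after every `reset_interval` metres (50 m) the offset resets to a fresh
zero-mean draw with σ = `reset_sigma` (0.2 m, a desk-scale stand-in for an
acoustic fix). Georeferencing annotations *naively* from this track —
vehicle position plus altitude-scaled image offsets onto an assumed flat
floor (`naive_georeference()`) — reproduces the qualitative field
phenomenon: repeated sightings of the same feature land decimetres apart
under drifting navigation while optical reprojection of the same pixels
agrees to numerical precision, and footprints that the noisy track declares
disjoint in fact overlap.

What passing on synthetic scenes does **not** show: the generator plants
exact cameras, an exact mesh, and noise-free pixel annotations. Real
surveys add pose error from bundle adjustment, mesh error from dense
matching and Poisson smoothing, and human pointing error — all of which
dominate real accuracy (centimetres on gentle terrain, decimetres on rugged
relief). The synthetic results certify the *machinery* (geometry, indexing,
bookkeeping, formats), not field accuracy.

## Problem sizes in the validation battery

The checks in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` run at sizes chosen to exercise the code paths well
past their leaf cases while staying desk-sized: 1000 random rays against a
500-triangle soup for the BVH/exhaustive-scan comparison; 1000 random
camera/point pairs with $|k_1| \le 0.2$ for projective round trips; two
40 × 8 m, 3-transect surveys (sinusoidal and random-field, ≥ 60 features,
~370 cameras, ~40 k faces) for ground-truth recovery and conservation; one
drifting-navigation survey for the mismatch and duplicate-recall analysis;
100-point geodesy round trips at up to 10 km; and 50 interior footprints
(12 for the exhaustive comparison) for disjoint selection.

## Known limitations

- Fisheye/omnidirectional cameras, tangential distortion and rolling
  shutter are out of scope; inputs using them are rejected, not
  approximated.
- Circles are reprojected at their center with a radius estimated from one
  rim point; on steep relief the true projected outline is not a circle.
- Overlap fractions use convex hulls of footprint projections; strongly
  non-convex footprints (extreme relief) have their overlap overestimated.
- The exhaustive disjoint solver is exponential and capped at 20 images by
  design; it exists as a reference, not a production path.
- `select_disjoint` maximizes nothing globally; it is a greedy filter whose
  admissibility, not optimality, is guaranteed.
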