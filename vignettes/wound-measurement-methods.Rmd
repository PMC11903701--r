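---
title: "Measuring wound areas from depth maps: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring wound areas from depth maps: models, phantoms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burnmetry)
```

## The measurement problem

Clinical wound documentation still leans on 2D photographs, but a wound on
a curved body surface projects onto the image plane with foreshortening:
planimetry on the photo reports the area of a *projection*, not of the
skin. With consumer depth sensors (192 × 256 LiDAR grids on phones and
tablets), every pixel also carries a distance, so the wound surface can be
reconstructed and measured in 3D. `burnmetry` implements that measurement
chain and, just as importantly, a way to *validate* it: synthetic limb
phantoms whose wound areas are known exactly by construction.

Throughout, image pixels are 0-based with `(u, v) = (column, row)` at pixel
centers; depths are z-depths in meters (distance along the optical axis,
not Euclidean ray range — this makes the pinhole equations exactly
solvable); lengths of body cross-sections are in centimeters, and all
reported areas are cm².

## Camera model

The pinhole model couples image, camera and world frames:

* intrinsics `K` (focal lengths `fx`, `fy`; principal point `ox`, `oy`)
  project camera-frame points to pixels;
* extrinsics `[R|t]` map world to camera coordinates,
  `p_cam = R p_world + t`.

Unprojection inverts the first step pixel-wise given the sensor depth
(`unproject_pixel()`, `unproject_depth_map()`), and the closed-form inverse
`Rᵀ(p − t)` recovers world coordinates (`camera_to_world()`). A grid cell
is *valid* iff its mask bit is set and its depth is finite and positive;
missing returns are never interpolated in this layer — interpolation policy
is a measurement-layer concern, and the measurement layer chooses exclusion
(see coverage, below). Lens distortion and depth-to-RGB registration are
out of scope; the package treats intrinsics as explicit input at the depth
grid's resolution.

## 2D projection area

The wound's outer contour is traced on the mask (Moore-neighbor boundary
tracing with Jacob's stopping criterion, on 4-connected components, with a
fixed counter-clockwise orientation), lifted to world coordinates, and its
best-fit plane is found with Newell's method — the classical robust polygon
normal. Contour points are projected onto the plane and the area is the
absolute *signed* (shoelace) polygon area in a fixed in-plane orthonormal
basis.

A note on the signed form: an unsigned triangle-fan (Heron) decomposition
of the projected polygon equals the signed area for convex contours but
over-counts concave fans, so the signed form is used; it is exact for every
simple polygon. Self-intersecting contours are flagged with a warning and
the signed value is still returned. The in-plane basis (world x-axis
projected into the plane, y-axis fallback) does not affect the area; fixing
it makes outputs bit-reproducible.

## 3D surface area

The curved surface is approximated by scanning all 2 × 2 pixel quads of
the wound from the top-left to the bottom-right, splitting each quad along
its top-left→bottom-right diagonal, and summing triangle areas computed by
a numerically stabilized Heron formula (sorted sides, clamped radicand, so
needle triangles cannot yield negative radicands). Two deliberate choices:

* **Diagonal.** The top-left→bottom-right split matches the scan order; a
  test verifies that the opposite diagonal changes the result by less than
  the discretization error.
* **Boundary inclusion.** A triangle contributes iff *all three* vertices
  are valid masked cells. Nothing is extrapolated beyond the segmented
  wound; the price is a systematic half-pixel erosion of the rim,
  quantified below. The `coverage` field — fully valid masked quads over
  fully masked quads — surfaces depth holes; wounds under 95% coverage are
  flagged.

Multi-wound images are measured per 4-connected component with a
*per-wound* best-fit plane, and totals are sums across wounds. (Whether a
single global plane would be preferable for multi-wound images is an open
modelling question; per-wound planes are consistent with summing wounds
independently.)

## Curvature model

Body cross-sections are modelled as ellipses measured by their full axis
lengths `a ≥ b` (what a caliper reads): the flat vertex has curvature
`b/a²`, the sharp vertex `a/b²`, and the circular limit `a = b = d` gives
`1/d`. Note this is a *diameter* convention — half the differential-geometry
curvature — kept because it is how such measurements are reported;
everything downstream (phantom radii `1/(2κ)`, `predicted_ratio()`) uses it
consistently. Reported curvatures are truncated toward zero at three
decimals (`curvature_report()`), matching how 7.0/7.4² = 0.12783… is
conventionally printed as 0.127.

`predicted_ratio(κ, A)` models a circular template of area `A` as a
geodesic disc wrapped on a circular cylinder of radius `R = 1/(2κ)` and
returns disc area over the area of its orthogonal projection onto the
tangent plane at the disc center,

  ratio(κ, A) = π r² / ∫₋ᵣʳ 2 √(r² − s²) cos(s/R) ds,  r = √(A/π),

evaluated by deterministic quadrature. Two independent checks are wired
into the tests: the closed form `2π r R J₁(r/R)` for the projection
integral, and the small-curvature expansion `1/(1 − r²/(8R²))`. The ratio
is continuous, strictly increasing in κ, depends on κ√A only, and the model
refuses discs wrapping beyond a quarter turn (`r ≥ πR/2`). A
constant-curvature cylinder is used even for elliptical sections (curvature
evaluated at the contact vertex): sites are summarized by a single
curvature number, and the approximation error is surfaced by comparison
tests rather than hidden. Compound anatomy (e.g. the dorsal hand, where a
small caliper curvature coexists with a large measured ratio) is explicitly
*not* claimed predictable by this single-curvature model.

## Limb phantoms and what they do (not) emulate

`wrap_template()` places a circular template of exact area on a parametric
surface. On developable surfaces (plane, circular/elliptical cylinders) the
disc is drawn in the unrolled plane and re-rolled, so its surface area is
exact by construction; on spheres the geodesic disc is the cap with
`2πR²(1 − cos θ) = A`. The default area is 43 cm² — 1/400 of a 17,000 cm²
adult body surface, rounded half away from zero. `ground_truth()` computes
the reference 2D projection area by dense deterministic quadrature of the
foreshortening factor; it is the brute-force oracle against which the
pipeline is tested.

`render_phantom()` ray-casts one ray per pixel against the closed-form
surface (no mesh, so ground truth stays analytic), records camera-frame
z-depth, and sets a mask bit iff the hit lies in the template region.
Defaults are the study conditions: 192 × 256 resolution, 0.27 m camera
distance (midpoint of a 25–30 cm capture protocol), no depth noise.
Remaining free choices, fixed once after a discretization analysis:

* **Framing.** Intrinsics are auto-fitted so the template fills the frame
  with a 4% border (anisotropic `fx ≠ fy`, i.e. the synthetic sensor fills
  both image dimensions). Rendering errors scale with metric pixel pitch,
  so the tool frames the wound the way a clinician would — filling the
  sensor.
* **Orientation.** Cylinder axes run along the 192-pixel image dimension,
  so the curved (wrap) direction gets the finer 256-pixel sampling, where
  foreshortening makes sampling most precious.
* **Noise.** Optional i.i.d. Gaussian z-depth noise (σ in meters, seeded);
  there is no public sensor noise specification, so the default is 0 and
  2 mm is a suggested robustness setting. The mask stays exact: emulating
  segmentation error is a different axis of variation (an erosion/dilation
  stress knob would belong there, not in the sensor model).

`simulate_cohort()` is the synthetic twin of a template study on
volunteers: representative per-site ellipse axes (`body_sites()`,
reproducing the observed curvature span 0.023–0.183 per cm), jittered per
subject by a common scale factor (σ = 8%) and a shape factor on the short
axis (σ = 3%), both truncated at ±2σ so extreme draws cannot wrap a 43 cm²
disc past the visible horizon. Renders are noiseless by default and every
run is seed-controlled.

What passing phantom tests shows: the geometry chain — unprojection,
contour tracing, plane fitting, triangulation — is correct to within
discretization on smooth convex surfaces. What it does not show: behaviour
on real skin (texture, specularity, sensor noise correlation), segmentation
errors (masks here are exact), concave or compound anatomy, and occlusion.
Clinical slopes and ratios from patient images are therefore context, not
test targets.

## Numerical behaviour and known limitations

The dominant error is boundary discretization. With triangles required to
have all three vertices inside the mask, the measured region is effectively
the true region eroded by about half a pixel along its rim. For the 43 cm²
disc framed on a 192 × 256 grid this is a deterministic ≈1% underestimate
of both areas (verified by the tests' resolution-doubling sequence: the
deficit halves per doubling and falls below 0.5% at 768 × 1024, below 0.2%
on the quarter-cylinder patch at 384 × 512). Because 2D and 3D areas are
eroded almost identically, the 3D/2D *ratio* is accurate to ≈0.2% at native
resolution — which is why the ratio, not the absolute area, is the robust
clinical quantity at this sensor resolution.

The erosion is amplified where the surface turns away from the camera: on
the most curved phantom tested (κ = 0.183 per cm, disc wrapping to ±78°),
3D recovery drops to ≈98.1% of truth at native resolution, just outside the
98.2–108.4% envelope the flatter phantoms comfortably satisfy. At twice the
resolution it recovers. Users measuring sharply curved, frame-filling
wounds at native LiDAR resolution should expect ≈2% absolute-area
underestimates; the ratio remains reliable.

Other numerical choices: Newell normals are rejected as degenerate when
their norm is below 1e−12 of the contour's squared extent; quadrature uses
composite Simpson with 20,001 nodes (the √ endpoint behaviour of the disc
integrand limits agreement with the Bessel closed form to ≈1e−7 relative,
far below measurement error); the depth file dialect stores float32, so
file round trips are bit-exact but in-memory vs through-file measurements
agree only to float32 precision (≈1e−7 relative); rigid-motion invariance
of areas holds to 1e−9 relative (bitwise identity under rotation is not
attainable in floating point). Statistical summaries use the sample (n−1)
standard deviation; regressions are unweighted OLS with intercept, and R²
is checked against the squared Pearson correlation.

## Problem sizes used in the test suite

Tests render at 96 × 128 up to 768 × 1024 (the latter only for the
oracle-equivalence battery), cohort simulations use 3–5 subjects over 2–11
sites, and every stochastic component is driven by fixed seeds. These sizes
were chosen as the smallest at which each claim is cleanly distinguishable
from discretization jitter.
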