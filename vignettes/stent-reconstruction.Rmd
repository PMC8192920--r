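---
title: "Reconstructing coronary stents in 3D from OCT: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing coronary stents in 3D from OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octstent)
```

## The reconstruction model

`octstent` rebuilds the 3D geometry of a deployed coronary stent from two
complementary data sources: intravascular OCT, which resolves the lumen
border and individual stent struts per cross-sectional frame but knows
nothing about vessel curvature, and an angiography-derived 3D centerline,
which supplies the curvature but no wall detail. The joining assumptions
are:

* **Frames sit perpendicular to the centerline.** Frame `i` is placed at
  arc-length station `i × frame_distance` (pullback speed × frame period)
  and embedded in the plane spanned by the local frame normal and binormal.
  No longitudinal motion compensation is attempted (cardiac-motion
  artifacts remain in the input data).
* **Roll is transported without twist.** The frame field along the
  centerline is a rotation-minimizing frame (RMF) computed with the
  double-reflection method. The alternative, Frenet frames, flips at
  inflection points and twists with torsion, which would corkscrew the
  reconstruction; RMF transport is the unique zero-twist choice, determined
  up to a single global roll angle.
* **The marker fixes absolute roll.** Every frame's imaged marker angle is
  subtracted, mapping the marker onto the RMF reference direction. For a
  physical marker transported consistently along the vessel this recovers
  absolute orientation, including per-frame catheter rotation drift.
  Frames without a marker inherit a rotation interpolated linearly (on
  unwrapped angles) between the nearest marked frames, held constant beyond
  the ends; this interpolation is our choice, as is the RMF itself — the
  workflow this package automates performed the equivalent steps inside a
  CAD environment without documenting its frame convention.

The catheter is assumed to lie on (or near) the centerline: unrolling and
the azimuthal contour parameterization treat the image origin as the
section center, and contours are required to be star-shaped about it.
Severely eccentric catheter positions would violate this and are not
modeled.

## Unrolling and its exact inverse

Stent contours and strut points are rotated with their frame's lumen
rotation, stacked on a straight axis, translated so the distal stent
contour centroid becomes the origin (distal, not proximal, as the anchor),
and unrolled: `x` is the station from the distal stent frame, `y` the arc
length along that frame's stent contour from the reference direction to
the strut's azimuth. Unrolling along the *stent* contour (not the lumen)
matches the role of the stent contour as the scaffold outline; where a
frame has strut points but no segmented stent contour, a convex closed
curve through the struts stands in.

Two details make the unroll/roll-back pair exactly invertible, which the
tests verify to 10⁻⁶ mm on noiseless phantoms:

* each frame's stent contour is resampled once into a canonical form (256
  points, equal arc length, anchored at azimuth 0), and both directions
  interpolate radius and arc length on that same polygon;
* the radial gap between a strut and the contour is stored with the planar
  point (`malapposition_mm`) and re-applied radially at roll-back, so
  malapposed struts survive the round trip at their true radius. Struts
  farther than 1 mm from the contour are additionally flagged and unrolled
  at their own radius rather than projected.

Internally the circumferential coordinate is carried as the azimuth; `y`
in millimeters is derived from it through the canonical contour. The two
are the same mapping — azimuth is simply the form in which the inverse is
exact and in which crowns are equally spaced regardless of lumen
ellipticity.

## Wireframe reconstruction

The planar wireframe step is manual in the workflow this package
automates; here it is algorithmic, with a scripted edit list
(`apply_manual_edits()`) preserving the operator's ability to correct
individual nodes. The builder follows four rules: consecutive peaks and
valleys of each ring joined into a closed zig-zag; links placed
consistently with the template's numbered link pattern; shadow gaps
bridged at the template's expected phase; and the pattern repeated across
the wrap seam.

Ring assignment is 1-D clustering on `x` with the template's ring pitch.
Within a ring, the crown pattern is located by least-squares fitting a
triangle wave in (azimuth, x) — phase by grid search (144 steps per crown
period) with local refinement, amplitude and midline in closed form, and
two rounds of robust residual trimming (3.5 × MAD, floor 0.005 mm) so
points lying on the inter-ring links do not inflate the crown amplitude.
Apex nodes take the *fitted* positions: the pullback samples the zig-zag
only at frame stations, so the extremal observed point systematically
stops short of the true turning point by up to one frame distance, whereas
the fit, pooling ~200 points per ring, recovers the apex essentially
exactly on noiseless data. An apex whose angular window contains no
observed point (wire shadow) is synthesized at the fitted position and
marked `bridged`; observed apexes inherit the median radial gap of their
window points (the median over ~10 points suppresses segmentation jitter
while preserving step changes at malapposition zone borders). Link
registration maximizes the number of observed points inside the inter-ring
gaps near the candidate link azimuths over all cyclic offsets of the
template's link pattern; ties take the smallest offset. The fitted crown
amplitude is checked against a prominence threshold (0.25 × crown height)
and the point-to-edge coverage radius (0.15 mm) is exposed in the
configuration; both defaults are ours, as the underlying rules are stated
only qualitatively.

One deliberate structural choice: links are explicit edges from a peak of
ring *r* to the facing valley of ring *r + 1* (as in planar stent
drawings), so a link junction has degree 3 (two zig-zag segments plus the
link) and plain crown apexes degree 2. The validity checks assert exactly
that, plus per-ring crown counts, link counts per ring pair, connectivity,
and seam periodicity.

## Roll-back, fillets, sweeping

Roll-back inverts the unrolling through the canonical contours, blending
equal-arclength-resampled contours linearly between bracketing frames
(inter-frame behavior is unspecified in the source workflow; linear
blending is our choice). Edge polylines are densified at 0.05 mm in the
planar metric before mapping so struts follow the lumen curvature, with
malapposition gaps interpolated linearly between end nodes. Crowns are
rounded with circular fillets of radius 1.5 × the strut half-width by
default (no value is documented for the original; this keeps the fillet
larger than the swept profile so the swept mesh cannot self-intersect at
apexes); an infeasible radius falls back per-apex to the largest feasible
one with a warning, and exactly collinear apexes are left untouched.
Sweeping orients circular profiles by an RMF along each edge; rectangular
profiles keep their wide face tangent to the wall by aligning the
thickness axis with the local radial direction, falling back to the sweep
RMF where no radial reference exists (e.g. strongly malapposed floating
struts). Each swept segment is closed with end caps and is individually
watertight; junctions are covered by the overlapping capped segments
rather than a boolean union — no constructive-solid-geometry engine is
used, and meshing for CFD happens downstream of the surface export anyway.

## Metrics

* **Stent length** is the arc-length extent of strut material along the
  centerline (not the chord), so curved stents report deployed length.
* **MSD**: cross-sections are cut perpendicular to the centerline every
  0.1 mm; the per-station diameter is the area-equivalent diameter
  `2√(A/π)` of the polygon through the strut crossings ordered by azimuth.
  The slice diameter of a zig-zag scaffold is intrinsically below the
  nominal tube diameter (the crossing polygon is inscribed); validation
  therefore always compares reconstruction and ground truth *measured
  identically*. "Stent diameter" has no unique definition for a point set;
  min/max Feret calipers are available behind the `method` argument.
* **Ellipse ratio** `X/Y`: furthest point pair over the maximum point-pair
  separation perpendicular to it, computed on the convex hull (which is
  exact for both maxima); ≥ 1 by construction, scale- and
  rotation-invariant.
* **Malapposition** is the signed radial distance from wireframe samples
  to the lumen wall (positive toward the lumen center), evaluated against
  the aligned lumen contours, exact for concentric fixtures.
* **Bland–Altman** reports the mean difference and `mean ± 1.96 sd`
  (sample SD). The printed agreement intervals in this literature behave
  as limits of agreement, which is what is implemented and labeled `loa`.
* **TAWSS** is the trapezoidal time average of |τ_w| over one cardiac
  cycle per surface element, the standard post-processing step for CFD
  results; the CFD solve itself is out of scope, the meshes are exported
  as STL/PLY/VTK for external solvers.

## The synthetic phantom and what passing tests mean

Physical validation of such pipelines uses stented silicone vessels imaged
by micro-CT. That ground truth is not reproducible in software, so the
package replaces it with a geometric phantom: the template wireframe is
wrapped onto the vessel wall (azimuth ∝ template y, station = template x
plus the stent's start margin), with malapposition zones offset radially
inward. Deployment is purely geometric — no mechanics — which suffices to
validate *reconstruction*, since reconstruction never models mechanics
either.

The pullback simulator emulates the features of OCT data that stress the
algorithm: frame sampling at 0.1/0.2 mm; strut points only where the
wireframe crosses a frame plane; a guidewire shadow sector (default 30°,
optionally drifting) deleting struts; catheter rotation drift (default
1°/frame) visible only through the marker; Gaussian segmentation jitter
(default SD 0.03 mm, on the scale of OCT axial resolution — neither the
jitter level nor the shadow width is documented for real data, so both
are configurable). It does **not** emulate: eccentric catheter position,
cardiac-motion frame misregistration, blood-clearance artifacts, tissue
protrusion, bifurcations, or overlapping stents. Passing the validation
suite therefore demonstrates the geometric fidelity and noise robustness
of the algorithm under idealized segmentations, not segmentation quality
or performance on pathological image data.

The validation suite (`phantom_suite_specs()`) fixes the study conditions:
six phantoms with deployment diameters 2.5–4.0 mm (the clinical size
range), straight and curved vessels (radius of curvature 20–30 mm,
typical of coronary segments), elliptic lumens up to axis ratio 1.5, one
tapered vessel, frame distance 0.2 mm for the smallest stent and 0.1 mm
otherwise, 8-crown rings with 3 links per pair, jitter SD 0.03 mm, and a
30° shadow. `scripts/acceptance.R` reconstructs all six end-to-end and
reports the Bland–Altman MSD bias, the mean ellipse-ratio difference, and
the reproducibility of two independent runs from identical inputs (the
pipeline contains no randomness, so that difference is identically zero;
the Bland–Altman machinery is still exercised to produce it).

## Numerical choices and degenerate inputs

* Tolerances: frame orthonormality 10⁻⁹; round-trip identity 10⁻⁶ mm;
  canonical contour resolution 256 points (radius error ~10⁻⁴ mm on a
  1.5 mm circle, cancelled exactly in the round trip by construction).
* Centerlines are interpolated linearly; inputs sparser than 1 mm are
  first smoothed with a natural cubic spline. Resampling preserves
  endpoints and realizes the largest spacing ≤ the request that divides
  the length evenly.
* Apex stations fitted marginally beyond the first/last stent frame are
  clamped within one frame spacing; farther is an error.
* Degenerate cases error early with typed messages: spacing ≤ 0,
  centerlines with < 2 distinct points, stations beyond the centerline,
  single-contour lofts, self-intersecting contours, missing markers,
  empty planar sets, missing templates (cannot-bridge), zero-length sweep
  edges (skipped with a warning), < 3 time points for TAWSS, collinear
  ellipse-ratio inputs.
* Problem sizes in the tests and acceptance script — six 16–18 mm
  phantoms at 0.1–0.2 mm frames, 5-ring 8 mm phantoms for unit fixtures,
  256-point canonical contours, 0.05 mm roll-back densification — were
  chosen so a single phantom reconstructs in seconds while keeping
  discretization error an order of magnitude below every tolerance they
  are tested against.

## Known limitations

* Absolute roll recovery presumes marker angles measured against a
  consistently transported reference; with real data the marker's world
  position must be identified once (e.g. from angiography), which is an
  input-preparation step outside this package.
* Contours must be star-shaped about the catheter center.
* Single stents only: overlapping or bifurcation double-stent patterns
  are not modeled, and the template must match the implanted stent's
  crown/link topology.
* The swept volume is a surface union of capped segments, not a single
  boolean solid; downstream volume meshers handle the overlaps.
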