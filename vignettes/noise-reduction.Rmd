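---
title: "Selective noise reduction for vessel surfaces from low-resolution images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective noise reduction for vessel surfaces from low-resolution images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselsmooth)
```

## The problem

Checkup CT images cover the whole neck and head at roughly 0.7 mm per
pixel, so a carotid lumen of ~7 mm diameter is resolved by about ten
pixels. A surface segmented from such an image is corrupted by two error
sources with very different spatial scales: high-frequency faceting from
the triangulation, and *low-frequency* error at the voxel wavelength —
staircase steps and partial-volume wobble of amplitude up to half a voxel,
i.e. ~5–10% of the vessel diameter. The second kind is the damaging one
for hemodynamics: it survives generic mesh smoothing (its wavelength is
far above the mesh edge length), it inflates the surface roughness, and it
seeds spurious near-wall vortices that bias wall-shear-stress (WSS)
estimates upward. Smoothing hard enough to remove it with a generic
Laplacian/Taubin filter shrinks the lumen, which raises the mean velocity
and biases WSS the other way.

`vesselsmooth` instead rebuilds the surface along the direction in which
the noise is structured. Coordinates are expressed in a right-handed frame
with the x axis along the image slice direction, all units mm.

## Pipeline

**Partition.** Points are grouped into slices along x and each slice is
split into connected components. A slice-wise component count of one marks
the parent vessel (Part 1), two marks the branches (Parts 2/3), and all
points within `k·Δx` (default k = 3 slices) of the slice where the count
changes form Part 4, the mixing zone around the bifurcation. Component
linking uses single linkage at 1.5·Δx on coordinates snapped to the
image's own Δx grid; the snap phase is estimated by a circular mean of the
fractional voxel offsets, which makes the clustering immune to sub-voxel
segmentation jitter while leaving truly off-grid clouds unchanged. The
branched region is taken as the terminal run of two-component slices;
isolated flickers near the transition are folded back into the parent.

**Cross-sections.** Each slice's points are mapped onto the y–z plane at
its center (half-open membership `|x − plane| < Δx/2`, so each point
belongs to exactly one plane), ordered by angle around the contour
centroid, and resampled by linear interpolation at `N = round(P/ΔL)`
exactly equal arc steps (ΔL = 0.1 mm). A fixed N per part — from the
median perimeter — gives every contour the same point count, which the
next step requires. Angular ordering assumes star-shaped contours; vessel
lumens satisfy this, strongly concave slices would not (a documented
limitation).

**Generator alignment.** The contour start indices are aligned across
sections by minimizing the sum of squared distances to the previous
section over all cyclic shifts and both orientations (computed exactly via
FFT cross-correlation of y + iz). Afterwards a fixed contour index traces
a longitudinal *generator curve* (y_g(x), z_g(x)) — the 1-D series on
which the noise model is simple: per-slice segmentation errors appear as
outliers at the 0.7 mm knot spacing.

**Judgment filter.** For each generator reference point, the mean,
population standard deviation, and median of the window of two reference
points before and after (five points, center included, ±1.4 mm) are
computed from the unfiltered series; a point outside the open interval
(mean − qσ, mean + qσ) is replaced by the window median. Defaults: q = 1,
one pass; decisions are taken on the original series, so a pass is
order-independent. Two design points deserve emphasis:

* *The window is counted in reference points, not dense samples.* The
  window must straddle the noise wavelength (the voxel pitch) to see it; a
  ±0.2 mm window on the densely interpolated curve judges only local
  curvature and leaves voxel-scale noise in place (that variant is kept as
  `filter_domain = "dense"`). With the reference-point window the phantom
  roughness drops by ~50%; with the dense window, by ~14%.
* *Series ends are never edited.* A truncated 3-sample end window flags
  every locally monotone end (on a ramp with step h, |v − mean| = h while
  σ = 0.816 h), which would systematically clip the sloped branch ends —
  measured as a 2–3% volume loss before the rule was introduced. Samples
  without a full 2m+1 window are left alone.

At q = 1 roughly a quarter of the reference points of a noisy phantom are
edited — most coordinate points pass through unchanged, which is why the
enclosed volume barely moves.

**Splines and loft.** Each filtered generator is interpolated with a
natural cubic spline (C2 at interior knots; zero second derivative at the
ends, the standard parameter-free closure) and evaluated every 0.1 mm.
Successive dense sections are joined as quad strips, inlets/outlets are
capped with centroid fans, and the bifurcation is closed by a cyclic
"zipper": the two first branch contours are merged into one loop at their
nearest-vertex bridge, the loop is zipped to the last parent contour by
shortest-diagonal marching, and the bridge is sealed with a saddle quad.
Part 4 points are not lofted: the circle through the bifurcation point and
one reference point per branch (`inscribed_circle_section()`) classifies
them, but it is a saddle-plane circle, not a lumen cross-section, so the
junction surface comes from the stitch instead. Watertightness and
consistent orientation are asserted, not assumed — a failed stitch is an
error. Exactly coincident vertices (filtered generators may touch) are
welded before the check so collapsed quads degenerate cleanly.

## Evaluation metrics

*Roughness.* Every generator profile (both y(x) and z(x)) is cut into
dX = 5 mm sections; per section a least-squares line is fitted, the
coordinates are rotated so the line is horizontal, and
Ra = (1/L)∫|h|dX is integrated by the trapezoid rule. R̄a pools the mean
over all sections of all curves. Two properties worth knowing: the
rotation makes Ra the *perpendicular* deviation, so a linear trend of
slope s scales it by cos(atan s) — negligible at vessel slopes; and a
sinusoid of amplitude A gives Ra = 2A/π only in the phase that is even
about the section center (an odd phase correlates with the reference
line).

*Volume.* Divergence-theorem volume of the closed mesh,
V = |Σ v₁·(v₂×v₃)|/6. The "original" volume is the loft of the raw,
unfiltered sections, so raw and smoothed volumes are measured by the same
instrument; open meshes are refused.

*WSS utilities.* τ = μ·u_p/y_p from the near-wall cell (μ = 0.004 Pa·s,
ρ = 1050 kg/m³ defaults); surface-averaged WSS as the area-weighted mean
of |τ|; TAWSS as the trapezoid time average over one period; area-weighted
histograms of the signed flow-direction component τ_x (positive opposite
the flow); and the four-harmonic Fourier inlet waveform with per-inlet
area A_art and amplitude coefficient β (LCA/RCA 4.52/4.80 × 10⁻⁵ m²,
β = 3.85 × 10⁻⁵; LVA/RVA 1.79/1.51 × 10⁻⁵ m², β = 3.77 × 10⁻⁵), whose
bracket term averages a₀ = 0.26 m/s over a period. The period is not
fixed by the model; T = 1 s is the configurable default. The printed flow
expression Q = A·β·bracket has awkward units if the bracket is read as a
velocity, so both the bracket and Q are exposed and the parabolic inlet
profile u(r) = (Q/A)(1 − (r/R)²) is computed exactly as printed; note its
area average is half the centerline value.

## The phantom generator

Testing needs geometries with known truth, so the package voxelizes
analytic vessels — straight tubes, torus-segment bends, and a
carotid-like bifurcation built from three capsule-swept cylinders meeting
at a point (default half-angle 25°, child diameters 0.8 and 0.65 of the
parent, carotid-like ICA/ECA proportions; parent diameter 7.1 mm and
length 50 mm in the standard configuration). A voxel is occupied iff its
center is inside the lumen on a pixel-center grid (centers at half-voxel
offsets, as on an image whose voxels tile the scene); the surface is the
set of occupied voxels with an empty 6-neighbor, minus the two flat cut
ends. Pure voxelization under-produces the roughness seen on real
segmentations, so each surface point is displaced radially within its
slice by Uniform(−a, +a) with a = 0.35 mm (half a voxel) by default —
a seeded, reproducible stand-in for partial-volume and threshold noise.
What the phantom does *not* emulate: intensity-dependent bias, motion
artifacts, anisotropic slice thickness, and real lumen eccentricity; a
pass on the phantom shows the pipeline removes grid-structured noise
without volume loss, not that it handles every pathology of clinical
segmentations.

Standard problem sizes used throughout the tests: the bifurcating phantom
at 0.7 mm voxels yields ~2,200 surface points and a smoothed mesh of
~10⁵ vertices; a full pipeline run takes a few seconds, and the complete
suite a little over a minute.

## Numerical choices and degenerate inputs

Vertex deduplication tolerance is 1e-6 mm (far below voxel scale);
contour resampling snaps sample positions onto polygon vertices within
1e-12·P and normalizes the start to the angular minimum, making
resampling idempotent on already-equispaced contours; ties in the
bifurcation-point search break on smallest x, then y, then z; fewer than
three sections fall back to linear interpolation with a warning; slices
whose contour is degenerate (collinear) are dropped with a warning;
vessels entering the image with branches first are mirrored internally
and mirrored back. The Taubin baseline uses uniform 1/|N(i)| weights
(cotangent weights are deliberately out of scope) and exposes both a
single-weight mode and the λ/μ pass-band mode with μ solved from
k_PB = 1/λ + 1/μ.

## Known limitations

Trifurcations and slices with more than two lumen components are
rejected; strongly non-star-shaped cross-sections would scramble the
angular ordering; the junction surface is a straight stitch across the
Part 4 gap (≈ 2k·Δx long), so sub-voxel detail of the flare is not
reconstructed there; and roughness is measured on the generator curves,
which is paired and consistent between raw and smoothed surfaces but is
not a mesh-intrinsic (e.g. spectral) roughness measure.
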