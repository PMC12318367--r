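---
title: "Simulating infill radiograph artifacts from G-code"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating infill radiograph artifacts from G-code}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`printdrr` simulates the radiograph of an FDM 3D-printed part from its
G-code, and quantifies how the projection angle changes the artifact the
infill lattice leaves on the image. This vignette documents the model,
the choices behind it, and what the package's tests do and do not
establish.

## The model

### Virtual printing

A G-code file is an ordered list of linear moves; a move with positive
extruder feed `ΔE` deposits material along its path. We model each such
move as a **bead**: a prism whose footprint in the build plane is the
stadium (capsule) of width `w` swept along the move's XY path, and whose
vertical extent is `(z_end − h, z_end]`, with `h` the layer height. The
bead width conserves extruded filament volume,

    w = ΔE · A_fil / (L · h),     A_fil = π d_fil² / 4,

with `L` the move length and `d_fil` the filament diameter (1.75 mm by
default). For the default constants a 10 mm move with `ΔE = 0.5` mm gives
`w ≈ 0.60` mm. This is a deliberate idealization: real beads have rounded
(oblate) cross-sections and spread with temperature; the rectangular
cross-section with stadium footprint is the simplest shape that conserves
volume and respects the move's centerline and layer height. Retractions
(`ΔE < 0`) are travels; stationary de-retraction primes are counted and
discarded rather than deposited as spurious blobs.

The **virtual print** is a binary voxel volume (isotropic 112.5 µm
spacing by default): a voxel is occupied iff its center lies inside any
bead. The binary voxel-center rule, rather than fractional coverage, is
chosen because the downstream projector treats the object as a binary
material/no-material field; partial-volume weighting would amount to a
different (grayscale) object model. Consequences of the rule are
measurable and bounded in the tests: total occupied volume matches the
extruded filament volume within 10% at the default spacing (overlaps at
wall crossings remove a few percent; grid-phase effects add a few), and
halving the spacing changes the total volume by under 5%.

### Digitally reconstructed radiographs

A radiograph here is a **path-length map**: for each detector pixel, the
total length (mm) of its ray's intersection with occupied voxels,
computed by exact incremental (Siddon-style) ray–grid traversal. There is
no spectral or attenuation model — the object is binary, so path length
is the projected quantity; `path_to_intensity()` provides an optional
monochromatic Beer–Lambert mapping for display only. Exact traversal
rather than interpolated ray sampling matters because the artifact
extrema come from razor-sharp alignment of thin walls with the beam;
trilinear sampling blurs exactly the feature being measured.

Geometry: the part stays fixed; the ray direction rotates. The **tilt**
is the angle between the central ray and the build (Z) axis, the
**tilt-axis azimuth** the in-plane direction of the rotation axis. With
axis `a = (cos α, sin α, 0)` and `m = ẑ × a`, the ray direction is
`d(θ) = sin θ · m − cos θ · ẑ`. The default beam is parallel: at the
clinical source–image distance of 1000 mm a 40 mm part subtends a cone
angle near 1°, and the package's own cone mode (point source at SOD,
detector at SID) converges to the parallel image in that limit, as the
projector tests verify. Detector pixels default to 150 µm; the detector
auto-sizes to the volume's rotated footprint plus a 2 mm margin.

One numerical point deserves note: point sampling of 112.5 µm voxel
columns with a 150 µm pixel comb (ratio 4:3) aliases, so total image
"mass" (Σ path · pixel area) is only approximately conserved at the
default pitch. The conservation property is exact when the detector pitch
matches the voxel pitch — one ray per voxel column — and that matched
configuration is what the mass-conservation test asserts to 1%.

### The artifact metric

The quantity of interest — "artifact" — is the structured non-uniformity the
lattice imprints within the part's shadow. We score a radiograph by the
**population standard deviation of path length** inside a region of
interest: the largest connected component of pixels above a path-length
threshold, holes filled, then eroded by `3 × extrusion width` (1.35 mm by
default). The erosion strips the high-contrast perimeter-wall rim, so at
moderate tilts the statistic tracks infill non-uniformity. The sd is
invariant to adding a constant (solid top/bottom skins shift, but do not
create, artifact at normal incidence) and scales linearly with the path
lengths; both properties are tested. A `peak_to_peak` variant is kept as
a secondary, outlier-sensitive metric.

`sweep_angles()` evaluates the metric over a tilt range — `[0°, 90°]` in
0.5° steps for the reference analyses — and `find_extrema()` locates the
coarse argmin/argmax and refines each by golden-section search on a
user-supplied callable down to 0.25° by default, with ties broken toward
the smallest angle and an optional symmetry period for reporting.

## The built-in slicer and what it emulates

`generate_part()` fabricates the test specimens: regular hexagonal
prisms, sliced into layers with concentric perimeter loops (insets at
`(i + ½)·w`) and infill clipped to the innermost inset shrunk by `w/2`.
Feeds are the exact inverse of the bead-width formula, so slicer and
voxelizer agree on bead geometry by construction. The reference specimen
is 40 mm across flats, 10 mm tall, with 2 perimeters and no solid skins:
skins only offset the path length uniformly at 0° and blur extremum
localization, so they are omitted for artifact analyses (a preset with
3/4 solid layers suits image-comparison use).

- **Grid**: two orthogonal line families at the pattern azimuth (45° by
  default, the common slicer convention) and azimuth + 90°, spacing
  `s = 2w/ρ` (each family contributes `w/s` of area), identical on every
  layer — continuous vertical walls.
- **Cubic**: three families 120° apart, spacing `s = 3w/ρ`, each family
  shifted along its *negative* normal by one layer height per layer, so
  each sweeps planar walls inclined 45° to the build axis — the diagonal
  faces of a corner-standing cubic lattice. The common shift chirality is
  deliberate: with the sweep convention above, the primary family's walls
  become beam-aligned at a tilt of exactly +45°, while the other two
  families' alignment angles (`tan θ = 1/cos 120° → 116.6°`) fall outside
  the swept quadrant. Alternating chirality would instead split the
  alignment between +45° and +63.4°.
- **Gyroid**: layer toolpaths are zero isocontours of
  `sin(kx)cos(ky) + sin(ky)cos(kz) + sin(kz)cos(kx)`, `k = 2π/P`,
  extracted by marching squares at a grid fine enough that chords stay
  below `w/2`, then projected onto the isosurface by damped Newton steps
  (the damping caps steps near the surface's saddle points, where the
  in-plane gradient vanishes). The period `P` is calibrated by bisection
  so that the mean contour length per unit area over one z-period, times
  `w`, equals the target density: contour density varies substantially
  with z, so the calibration averages twelve slices. For ρ = 0.15 and
  w = 0.45 mm this gives `P ≈ 7.2` mm.

For all three patterns at 15% density the voxelized fill fraction of the
infill region lands within 0.15 ± 0.02 (tested), so the three fixtures
are directly comparable.

What the fixtures do **not** reproduce: any particular slicer's exact
seam placement, anchoring loops, infill/perimeter overlap tuning, or
flow compensation; real dimensional noise, over/under-extrusion and
layer-bonding geometry. Conclusions from these fixtures are about the
idealized lattice geometry, not about any specific printed object.

## Choice of sweep axis

The tilt-axis azimuth is exposed as configuration because it changes the
physics of the sweep. `default_tilt_axis()` encodes the package default:

- For **grid**, the axis lies along the lattice's diagonal mirror plane
  (pattern azimuth − 45°), oblique to both wall families. An axis
  parallel to one family would keep the *orthogonal* family beam-aligned
  at every tilt (the ray never acquires a component along that family's
  normal), so its walls stay razor sharp, the metric grows like
  `1/cos θ`, and the angle dependence of the infill artifact is drowned.
  With the diagonal axis both families misalign symmetrically and the
  profile shows the expected structure: global maximum at 0°, interior
  minimum, mirror symmetry about 0° (tested on the small fixture).
- For **cubic**, the axis is the primary wall-family azimuth, which makes
  that family's inclined walls beam-aligned at +45°.
- For **gyroid**, the axis follows the pattern azimuth.

## Problem sizes and runtimes

The reference analyses voxelize a 40 × 10 mm hexagon at 112.5 µm
(≈ 450 × 390 × 125 voxels) and project 181 angles onto a ~150 µm
detector; one sweep takes on the order of half a minute in the compiled
projector, and the full three-pattern acceptance run a few minutes. Unit
tests run on 16–20 mm fixtures at 0.1125–0.2 mm spacing and finish in
seconds. The 225 µm "smoke" variant of the grid sweep (spacing above the
layer height, which the voxelizer flags) still localizes the grid
maximum at 0° and completes in well under two minutes.

## Known limitations

- **Grazing-angle dominance of the raw metric.** Near θ = 90° the beam
  lies in the build plane of a thin plate: the path length inside the
  silhouette ramps from ~7 mm (long chords through the hexagon) to near
  zero across the corner regions, and rays parallel to the physical
  layer planes accumulate layer-coherent paths. Both effects are real
  properties of the projection, but they are *external-geometry*
  artifact: the eroded-silhouette sd cannot distinguish them from infill
  non-uniformity, because the corner ramp spans ~10 mm while the erosion
  margin is 1.35 mm. For grid and cubic the infill-driven extrema still
  dominate the whole quadrant (argmax 0° and 45°). For gyroid — the
  pattern with the *least* infill artifact, hence the least infill-driven
  contrast — the 75–90° shoulder exceeds the clear infill-driven interior
  maximum at 45°, so the global argmax over [0°, 90°] reports the
  edge-on view rather than the unit-cell diagonal. Restricting the sweep
  to tilts below ~70°, or detrending the macroscopic thickness profile
  before taking the sd, isolates the lattice signal; both are left to
  the caller because they change the metric's definition.
- **Minimum-artifact angles are dimension-sensitive.** The interior
  minimum arises where wall smears overlap most uniformly, which depends
  on part height, hexagon width and perimeter count; specimens of other
  dimensions shift it by many degrees. The robust, tested property is an
  interior minimum in (0°, 45°) with less than half the maximum's
  metric, not any particular angle.
- **No exposure physics.** Spectra, scatter, detector blur and noise are
  out of scope; outputs are path lengths of a binary object. Visual
  film-like rendering is a display transform only.
- **Dialect coverage.** The parser supports the Marlin/Prusa linear-move
  subset (G0/G1, G90/G91, M82/M83, G92, mm units); arcs (G2/G3) are
  rejected unless explicitly skipped, and inch mode is an error.
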