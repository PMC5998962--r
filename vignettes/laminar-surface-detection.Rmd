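---
title: "Detecting cortical laminar surfaces in 3D histological volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cortical laminar surfaces in 3D histological volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminae3d)
```

## The problem

Cell-body-stained histology resolves the six-layered cytoarchitecture of the
human isocortex at micrometre scale, but classical sections are 2D: only
cortex cut nearly perpendicular to the surface can be measured, measurements
are inflated by oblique cutting angles, and manual delineation does not scale
beyond a handful of samples. Given a 3D reconstruction of stained sections —
an isotropic intensity volume in which bands of cell bodies are visible in
any oblique plane — together with paired white and pial surface meshes whose
vertices are linked one-to-one, laminar structure can instead be analysed
*surface-wise*, at every cortical location at once.

`laminae3d` implements such a pipeline. It detects two intracortical
surfaces with distinct, area-robust signatures in the staining-intensity
profile:

* the **layer I/II boundary** — the sharp rise in cell density from the
  nearly cell-free layer I into the dense layer II, visible as a peak in the
  first derivative of the profile close to the pial surface; and
* a **mid-layer IV surface** — the prominent mid-cortical intensity peak of
  the granular layer, present in most (not all) cortical areas.

Everything downstream — laminar depth maps, the curvature dependence of
layer IV depth, oblique-sectioning error maps — is built from these two
surfaces.

## Data model and conventions

An `intensity_volume` is a 3D array at isotropic voxel size (µm) with a
fixed (x, y, z) axis order; voxel `[i, j, k]` has its center at
`origin_mm + (c(i, j, k) - 1) * voxel_size_um / 1000`. Surface coordinates
are millimetres; voxel sizes and distance errors are micrometres, matching
the field's mixed conventions, and all conversions are centralised in
`world_to_voxel()` / `voxel_to_world()`. Intensity follows the histological
convention background = 0, increasing with staining intensity;
`invert_intensity()` brings raw bright-background scans into this
convention. Profiles are indexed from the pial (or layer I/II) end, sample 1,
to the white end, sample `n`; all fractional depths share this orientation.

Large volumes are processed through `decompose_blocks()`: the grid is
partitioned into non-overlapping cores, each extended so adjacent blocks
overlap by at least a configurable margin. With an overlap at least the
cortical height, every straight profile lies entirely inside some block, so
block-wise smoothing never contaminates profile ends (the suite verifies
this by brute force over random segments).

## Anisotropic volume smoothing

Histological artifacts — local staining variations, microtome defects —
add high-frequency intensity noise that fragments profiles into dozens of
spurious peaks. `anisotropic_smooth()` removes it with an explicit
nonlinear-diffusion scheme that smooths *along* iso-intensity contours
(i.e. along layers) at full strength and *across* them through the
diffusivity `g(|∇I|) = 1 / (1 + (|∇I|/κ)²)`. Each step splits the Laplacian
into the second derivative along the gradient and its tangential remainder
and advances

    I ← I + dt · ( ΔI − I_ηη + g(|∇I|) · I_ηη )

Parameters, with defaults:

* `iterations = 9` — controls the overall smoothing extent;
* `time_step = 1/6` voxel² — the 3D explicit-stability bound;
* `edge_sensitivity κ = 15` intensity units/voxel — gradients far below κ
  are treated as noise, gradients far above (laminar boundaries) are
  preserved. The default sits between the post-reconstruction noise
  gradient scale (≈ 7 for noise σ = 5) and the weakest interlaminar step
  of the phantom (≥ 20 per voxel).

The smoothing extent is reported as the *maximum resultant FWHM*: in the
linear limit (κ → ∞) each step adds kernel variance `2·dt` voxel², so
`FWHM = voxel · sqrt(8 ln 2 · 2 · iterations · dt)`; `estimate_max_fwhm()`
implements this closed form, and the suite verifies it against the measured
impulse response. The defaults give 0.163 mm at 40 µm voxels. Because cross-
gradient diffusion is slower, this is an upper bound for the nonlinear
operator — hence *maximum* FWHM. A hard range clamp enforces a discrete
maximum principle (the cross-derivative stencil alone does not guarantee
it).

The level of smoothing is not chosen by eye: `select_smoothing_level()`
increases the iteration count from zero until the *median number of profile
peaks* (strict interior maxima with topographic prominence ≥ 5% of the
profile range, `count_profile_peaks()`) falls within a target range,
default 3–5 — the count expected from six-layered isocortex (peaks at
layers II, IV and VI) with occasional sublayers. Flat plateaus in
noise-free synthetic profiles are counted as single peaks.

## Profiles

`extract_profiles()` samples the volume at `n = 100` equidistant points
along the straight chord between each linked pial/white vertex pair
(trilinear interpolation; chords, not curved streamlines, because vertex
linkage defines straight traversals). Zero-length chords are masked rather
than raising errors. Endpoints within half a voxel outside the grid are
clamped; anything farther errors — surfaces that far outside the volume
indicate mismatched inputs.

`simulate_von_economo_profile()` turns a per-layer thickness/density table
into the histogram-like laminar density profile classically derived from
quantitative cytoarchitectonic measurements: density as height, thickness
as width, smoothed with a Gaussian whose FWHM is a fraction of the total
thickness (default 0.054 ≈ 0.163 mm on a 3 mm cortex, mirroring the volume
smoothing). These simulated profiles motivate the two detection heuristics;
the shipped table (`inst/extdata/synthetic_area_table.tsv`) is a small
*synthetic* illustrative set — granular, agranular and occipital-type
areas — not a transcription of any atlas; users supply real tables in the
same four-column schema.

## Layer detection

### Layer I/II boundary

Initialization uses the tissue classification where available: the first
profile transition from the layer I label to the gray (II–VI) label.
Otherwise the boundary starts 200 µm below the pial surface (the expected
layer I thickness). Refinement then iterates two corrections
(`refine_layer12()`):

1. **Gradient adjustment** — each vertex moves to the *closest* local
   maximum of the profile's first derivative. Ties (two equally distant
   maxima) break toward the pial side, since spurious deep gradient maxima
   (layer III/IV transitions) are the dominant failure mode.
2. **Intensity matching after on-surface smoothing** — the intensity values
   at the adjusted positions are smoothed across the mesh by three
   iterations of nearest-neighbour averaging, and each vertex moves to the
   position (by linear interpolation between samples) whose intensity
   matches its smoothed value, choosing the match nearest in depth. A
   vertex with no match, or whose match lies deeper than 200 µm below the
   pial surface, takes the average depth of its neighbours instead — this
   is what heals isolated misplaced vertices.

### Equivolumetric depth

The equivolumetric model states that layers conserve their *volume*
fraction across folds, not their distance fraction: layers are deeper (by
chord fraction) in sulcal fundi and shallower on gyral crowns.
`compute_equivol_field()` implements it per vertex in closed form: the
cortex around a linked vertex pair is modelled as a truncated prism whose
cross-sectional area interpolates linearly from the local upper-surface
area `A_u` to the local white-surface area `A_w` (per-vertex barycentric
areas), so the surface at volume fraction `f` sits at chord fraction ρ
solving

    (A_w − A_u)/2 · ρ² + A_u · ρ = f · (A_u + A_w)/2 ,

which reduces to ρ = f for parallel surfaces. We chose this closed form
over a voxel-wise PDE/advection solver: it is exact for the prism model,
deterministic, meshsize-independent, and the suite pins it against the
concentric-sphere analytic solution, a voxel-counting oracle and the
analytic folded-cortex solution (all within 0.02 fractional depth).
`equivol_volume()` rasterizes the field into a voxel grid by chord
sampling when a volumetric representation is needed.

### Mid-layer IV surface

Profiles are re-extracted between the detected layer I/II surface and the
white surface, so that layer IV is sought within the cell-dense cortex
only. Initialization (`init_layer4()`) takes the first profile peak, with
prominence at least 15% of the profile range, that follows the first
*upward inflection after a descent* (first derivative positive, second
derivative positive, preceded by a negative-gradient sample). The upward
inflection marks layer II/III more reliably than the layer II peak itself;
requiring a preceding descent prevents the initial rise into layer II from
qualifying, which would capture the layer II peak. Vertices with no
qualifying peak — agranular cortex — are marked *unresolved*.

Refinement (`refine_layer4()`) iterates three corrections:

1. **Taubin mesh smoothing** (alternating λ = 0.33 / µ = −0.34 umbrella
   steps, shrinkage-free) of the current layer IV mesh, re-projected onto
   the chords;
2. **equivolumetric-depth smoothing** — positions are converted to
   equivolumetric depth, smoothed across the surface with a 10 mm FWHM
   Gaussian (`smooth_scalar_on_surface()`), and the surface is rebuilt at
   the smoothed depths. Unresolved vertices participate only here: they
   receive depth from their resolved surround and are never snapped to a
   peak;
3. **peak adjustment** — each resolved vertex moves to its nearest
   qualifying profile peak.

On-surface smoothing is iterated neighbour diffusion calibrated to the
requested FWHM through the mean squared edge length
(`FWHM² = 8 ln 2 · N · w · mean(|e|²) / 2`), verified against a planar
Gaussian on a regular grid. Masked vertices neither emit nor receive
weight.

### Convergence

Both refinement loops stop when the fraction of vertices that moved by
more than one profile sample step falls below
`convergence_max_moved_frac = 100/163842` — i.e. "fewer than 100 of
163,842 vertices", expressed as a fraction so the same rule scales to
meshes of any size, with the displacement threshold made explicit (one
sample step) since "changed location" is otherwise undefined on continuous
depths. Non-convergence at `max_iterations` warns and reports the
moved-vertex trace; on phantoms the trace is monotone non-increasing and
convergence takes a handful of iterations.

## Morphometry and sectioning error

`mean_curvature()` is the cotangent-Laplacian estimator,
`H = |L x| / (2A)` with barycentric areas, signed by the outward normal so
gyral crowns are positive and fundi negative (the estimator is pinned to
analytic sphere/cylinder values within 3–5%). Curvature is evaluated on
the mid-surface between the layer I/II and white surfaces; layer IV
position is expressed as `relative_depth()` — the percentage of the
layer I/II → white chord (percentage, not fraction, so regression
coefficients are in depth-points per mm⁻¹). Both maps are smoothed at 3 mm
FWHM before regression to remove isolated extremes, and vertices are
excluded where cortex is thinner than an implausible 0.5 mm or flagged
(medial-wall-type masks). `fit_curvature_depth()` fits linear, quadratic
and cubic OLS models and compares them with
`BIC = n·ln(RSS/n) + k·ln(n)`, `k = order + 2` (coefficients, intercept,
residual variance) — the Gaussian-likelihood form, made explicit here
because BIC conventions differ.

For 2D-sectioning error analysis, `section_angle()` computes
`α = arcsin(|N·(v_white − v_pial)| / |v_white − v_pial|)` — the magnitude,
since the thickness overestimation `100·(1/cos α − 1)` %
(`overestimation_error()`) is even in α and invariant to chord direction.
At α = 18° the overestimation reaches 5.1%.

## Validation against manual delineations

Manual delineations are consumed as named polylines (pial, layer I/II,
layer IV upper/lower limits, gray/white border) on axis-aligned section
planes. `surface_to_manual_distance()` intersects a detected surface with
the plane and measures nearest distances to the polyline, signed negative
toward white (orientation resolved against the white polyline — the
distance-difference rule handles arbitrary fold shapes).
`distance_tests()` runs the Anderson–Darling normality test (estimated
parameters; it needs ≥ 8 samples and reports `NA` below that) and a
one-sample t-test of zero mean error — two-sided by default with a
one-sided option, since "does the error differ from zero" is naturally
two-sided. `relative_depth_correlation()` pairs automatic intersection
points with the *nearest* point on the manual mid-layer IV line (arc-length
matching would require consistent parameterisations that real delineations
lack) and correlates the two relative depths. All statistics are pinned to
textbook-formula reimplementations at 1e-10 in the suite.

## The phantom: what it emulates and what it does not

`generate_phantom()` builds the entire test world: a sinusoidal mid-surface
`z = z₀ + A·sin(2πx/λ)` extruded along y, white/pial surfaces offset half a
thickness along analytic normals, and six laminar bands placed at constant
*equivolumetric* depth using the exact 2D offset-area solution — so the
chord-fraction depth of every band varies with curvature by construction,
which is precisely the geometric signal the pipeline must recover. Voxel
intensities take per-band levels (layer I dimmest at 20, layer IV
brightest at 95, layer VI a secondary peak at 65) plus seeded Gaussian
noise; labels, truth surfaces, analytic curvature and manual-style
delineations are all emitted consistently from the same geometry.

Defaults: 256 × 64 × 256 voxels at 40 µm, thickness 2.5 mm, wavelength
12 mm, amplitude 2 mm, noise σ = 5 (≈ 7% of the laminar dynamic range, a
realistic post-reconstruction noise level), 96 × 24 mesh vertices. The
amplitude is set against the self-intersection bound for offset surfaces
(minimum fold radius λ²/4π²A must exceed half the thickness; 2 mm leaves a
1.46× safety factor, and the constructor rejects violating
configurations). An `equidistant = TRUE` falsification mode places bands
at constant chord fraction instead: there the curvature–depth regression
slope must vanish, guarding against the pipeline hallucinating the
equivolumetric effect. An optional agranular patch removes the granular
peak by letting deep-band intensity decay monotonically toward the white
level, testing the unresolved-vertex pathway. The 1D companion
`phantom_profile()` adds a short white-matter tail (4% of samples),
emulating the partial-volume blend at the gray/white boundary so layer VI
forms an interior peak as it does in volume-sampled profiles.

What the phantom deliberately does **not** emulate: tissue tears and
staining inhomogeneities beyond additive noise, curvature along the
extrusion axis (folds are cylindrical), areal variation of band depths and
levels, cell-size effects on staining, and misregistered or imperfect
input surfaces. Passing the suite therefore demonstrates correctness of
the geometry and the detection logic under the stated noise model — not
robustness to every failure mode of real histology.

## Problem sizes and numerical choices

The test suite runs most module tests on a 128 × 24 × 160 phantom at 50 µm
(480 mesh vertices) and the acceptance properties on the full default
phantom; the whole suite completes in about a minute on one core. Other
fixed choices: explicit time step capped at the 3D stability bound 1/6;
tie-breaks toward the pial side; 1-sample convergence displacement
threshold; half-voxel endpoint clamping; prominence thresholds 5% (peak
counting) vs 15% (layer IV qualification — true laminar peaks reach ≥ 27%
of range, residual noise bumps in low-contrast agranular profiles stay
below ~10%); AD test requires n ≥ 8; degenerate inputs (constant volumes,
zero-length chords, zero-variance samples, constant correlation series)
return flagged results rather than errors wherever a masked result is
meaningful.

## Known limitations

* Only two surfaces are detected; full six-layer segmentation needs
  area-aware models beyond these two heuristics.
* The layer IV surface in agranular cortex is an equivolumetric
  interpolation from its granular surround, not a measurement.
* The equivolumetric closed form assumes linear area interpolation through
  the depth; strongly conical folds deviate at the third decimal of
  fractional depth.
* The FWHM estimator is exact only in the linear-diffusion limit; for the
  nonlinear operator it is an upper bound, and no per-direction effective
  FWHM is reported.
* Straight-chord profiles undersample strongly curved columns where true
  streamlines bend.
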