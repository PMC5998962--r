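# laminae3d

Automated detection of cortical laminar surfaces in 3D cell-body-stained
histological volumes.

## What it does, and for whom

High-resolution 3D reconstructions of stained histological sections make the
layered cytoarchitecture of the human cortex visible in any oblique plane —
but extracting *surfaces* that follow individual layers across the folded
cortex has to be automated: manual delineation is 2D, slow, and
observer-dependent, and measurements on 2D sections are inflated by oblique
cutting angles. `laminae3d` is for researchers working with volumetric
histology (or histology-like MRI contrasts) who have:

* a 3D scalar intensity volume *I* at isotropic resolution (NIfTI-1), and
* paired white and pial triangle meshes with one-to-one vertex linkage
  (Wavefront OBJ), so each linked pair (v_pial, v_white) defines a cortical
  traversal.

From staining-intensity profiles sampled at 100 equidistant points along
each chord, the package detects two surfaces with area-robust laminar
signatures:

* the **layer I/II boundary** — the position of the sharp rise in cell
  density from the sparse layer I into the dense layer II, found as a peak
  of the profile's first derivative near the pial surface, refined
  iteratively with on-surface intensity smoothing;
* a **mid-layer IV surface** — the prominent mid-cortical intensity peak of
  the granular layer, initialized after the upward inflection that marks
  layer II/III and refined by alternating shrinkage-free (Taubin) mesh
  smoothing, on-surface smoothing of *equivolumetric* depth, and
  nearest-peak adjustment, until fewer than a fraction
  100/163,842 of vertices move between iterations.

The equivolumetric model — layers conserve volume fraction, not distance
fraction, across folds — enters through a per-vertex closed form: with local
areas A_u (upper surface) and A_w (white), the surface at volume fraction
*f* sits at chord fraction ρ solving

    (A_w − A_u)/2 · ρ² + A_u · ρ = f · (A_u + A_w)/2 .

Supporting modules provide layer-preserving anisotropic volume smoothing
with automatic, peak-count-based selection of the smoothing level
(target: a median of 3–5 peaks per profile); simulated laminar density
profiles from per-layer thickness/density tables; cotangent-Laplacian mean
curvature and the curvature–depth regression with BIC model comparison
(BIC = n·ln(RSS/n) + k·ln n); the oblique-sectioning error geometry
α = arcsin(|N·(v_w − v_p)|/|v_w − v_p|), error = 100·(1/cos α − 1) %; and
validation statistics (signed/unsigned distances to manual delineations,
Anderson–Darling + t tests, Pearson correlation of relative layer IV
depth). A synthetic folded-cortex phantom with known laminar ground truth
makes the entire pipeline testable without any external data.

## Worked example

A 50 µm folded-cortex phantom, smoothed and run through the full detection
pipeline:

```r
library(laminae3d)

cfg <- phantom_config(grid_dim = c(128, 24, 160), voxel_size_um = 50,
                      mesh_nx = 48, mesh_ny = 10)
ph <- generate_phantom(cfg)
#> <phantom> 128x24x160 @ 50 um; A = 2 mm, lambda = 12 mm, t = 2.5 mm; 480 mesh vertices

smoothed <- anisotropic_smooth(ph$volume, smoothing_config())
det <- detect_layers(smoothed, ph$pair, ph$classification)
det
#> <laminar_detection>
#>   layer I/II: <layer_surface> [pial-white] 480 vertices (480 valid, 480 resolved); depth 0.069 (sd 0.010)
#>   layer IV:   <layer_surface> [layer12-white] 480 vertices (480 valid, 480 resolved); depth 0.380 (sd 0.036)
#>   qc: 0 masked, 0 unresolved; traces I/II [24 0], IV [0]
```

The layer I/II boundary sits at ~7% of the cortical depth (the phantom's
layer I band, placed equivolumetrically, is shallower on the gyral crown);
layer IV sits at 38% of the layer I/II → white chord on average, varying
with fold curvature. Against the phantom's analytic ground truth:

```r
mean(abs(det$layer12$depth_frac - ph$truth$layer12$depth_frac) *
     pair_thickness(ph$pair) * 1000)
#> [1] 9.185585        # mean unsigned placement error, um (voxel = 50 um)
```

Layer IV depth is then regressed on mid-surface mean curvature (both maps
smoothed at 3 mm FWHM, implausibly thin vertices masked):

```r
H  <- mean_curvature(mid_surface(det$layer12, ph$pair$white))
rd <- relative_depth(det$layer4, det$layer12, ph$pair)
msk <- H$mask & rd$mask & mask_vertices(pair_thickness(ph$pair))
fit_curvature_depth(
  smooth_scalar_on_surface(H$values,  ph$pair$white, 3, mask = msk),
  smooth_scalar_on_surface(rd$values, ph$pair$white, 3, mask = msk),
  mask = msk)
#> <curvdepth_fits> n = 368; selected order: 3 (lowest BIC)
#>        order   n       rss   bic    fstat p     beta1
#> order1     1 368 0.0550184 -3224   195984 0    -88.07
#> order2     2 368 0.0018279 -4471  2946788 0    564.28
#> order3     3 368 0.0001011 -5530 35410666 0 -14639.16
```

The linear slope is negative — layer IV is relatively deeper in negatively
curved fundi and shallower on positively curved crowns, exactly what
equivolumetric layering implies — and the cubic model wins the BIC
comparison. The sectioning-error formula at an 18° profile-to-section
angle:

```r
overestimation_error(18)
#> [1] 5.146222        # percent thickness overestimation
```

A thin command-line dispatcher over the same functions ships at
`inst/cli/laminae3d.R` (`invert`, `subsample`, `blocks`, `smooth`,
`profiles`, `detect`, `phantom`, `curvature`, `angle-error`).

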