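test_that("layer I/II initialization follows labels, falls back, and masks thin cortex", {
  ph <- small_phantom()
  profiles <- extract_profiles(small_phantom_smoothed(), ph$pair)
  init <- init_layer12(profiles, ph$pair, ph$classification)
  # layer I occupies the top 10% equivolumetric band (~0.06-0.09 chord frac)
  expect_lt(max(abs(init$depth_frac - ph$truth$layer12$depth_frac)), 0.05)
  # without labels: exactly 200 um below pial, as fraction of 2.5 mm
  init0 <- init_layer12(profiles, ph$pair, cls = NULL)
  expect_equal(unname(init0$depth_frac), rep(0.2 / 2.5, length(init0$depth_frac)),
               tolerance = 1e-9)
  # a vertex thinner than the fallback depth is masked
  thin <- slab_pair(nx = 3, ny = 3, spacing = 0.4, z_top = 1, thickness = 0.15)
  vol <- intensity_volume(array(1, dim = c(8, 8, 8)), 300)
  pthin <- extract_profiles(vol, thin, n = 10)
  ithin <- init_layer12(pthin, thin)
  expect_false(any(ithin$mask))
})

test_that("gradient adjustment picks the closest maximum, ties toward pial", {
  # profile with two equal-magnitude intensity rises at depths 0.3 and 0.5
  n <- 101
  x <- seq(0, 1, length.out = n)
  prof <- 50 * plogis((x - 0.3) / 0.01) + 50 * plogis((x - 0.5) / 0.01)
  pair <- slab_pair(nx = 3, ny = 3, spacing = 0.3, z_top = 1, thickness = 0.5)
  ps <- profile_set(matrix(rep(prof, 9), nrow = 9, byrow = TRUE), x,
                    rep(0.5, 9))
  start <- layer_surface(rep(0.4, 9), pair$pial$vertices, pair$white$vertices,
                         pair$white$triangles, frame = "pial-white")
  cfg <- detection_config(layer1_max_depth_um = 400, max_iterations = 4)
  out <- refine_layer12(start, ps, pair, cfg)
  expect_equal(unname(out$depth_frac), rep(0.3, 9), tolerance = 0.02)
})

test_that("an isolated misplaced vertex is pulled back to its neighbourhood", {
  ph <- small_phantom()
  profiles <- extract_profiles(small_phantom_smoothed(), ph$pair)
  init <- init_layer12(profiles, ph$pair, ph$classification)
  bad <- 200
  init$depth_frac[bad] <- 0.5 / 2.5          # 500 um deep
  init$coords <- init$upper_coords +
    init$depth_frac * (init$lower_coords - init$upper_coords)
  ref <- refine_layer12(init, profiles, ph$pair)
  nb <- mesh_neighbors(ph$pair$white)[[bad]]
  expect_lt(abs(ref$depth_frac[bad] - mean(ref$depth_frac[nb])), 0.03)
})

test_that("refined layer I/II tracks the sharp intensity step within one voxel", {
  ph <- small_phantom()
  det <- small_detection()
  err_um <- abs(det$layer12$depth_frac - ph$truth$layer12$depth_frac) *
    pair_thickness(ph$pair) * 1000
  expect_lte(mean(err_um[det$layer12$mask]), 50)   # one 50 um voxel
})

test_that("equivolumetric depth matches slab linearity and the spherical closed form", {
  pair <- slab_pair(nx = 6, ny = 6, spacing = 0.5, z_top = 2, thickness = 2)
  field <- compute_equivol_field(pair$pial$vertices, pair)
  rho <- runif(36)
  expect_equal(chord_to_equivol(field, rho), rho, tolerance = 1e-9)
  # concentric spheres: white r = 1, upper r = 2; f = 0.5 at r = 4.5^(1/3)
  white <- icosphere(3, 1); pial <- icosphere(3, 2)
  spair <- surface_pair(white = white, pial = pial)
  sf <- compute_equivol_field(pial$vertices, spair)
  nv <- nrow(white$vertices)
  rho_half <- equivol_to_chord(sf, rep(0.5, nv))
  rho_exact <- 2 - 4.5^(1/3)  # chord length is 1
  expect_lt(max(abs(rho_half - rho_exact)), 0.02)
  expect_equal(equivol_to_chord(sf, rep(0, nv)), rep(0, nv))
  expect_equal(equivol_to_chord(sf, rep(1, nv)), rep(1, nv))
  # inverse consistency
  f <- runif(nv)
  expect_equal(chord_to_equivol(sf, equivol_to_chord(sf, f)), f,
               tolerance = 1e-9)
})

test_that("equivolumetric closed form agrees with a voxel-counting oracle", {
  # brute-force volume fractions in the spherical shell between r=1 and r=2
  h <- 0.05
  g <- seq(-2.2, 2.2, by = h)
  r <- sqrt(outer(g^2, as.vector(outer(g^2, g^2, "+")), "+"))
  rs <- r[r >= 1 & r <= 2]
  white <- icosphere(3, 1); pial <- icosphere(3, 2)
  sf <- compute_equivol_field(pial$vertices, surface_pair(white, pial))
  for (f in c(0.2, 0.5, 0.8)) {
    r_oracle <- stats::quantile(rs, probs = 1 - f, names = FALSE)
    rho_oracle <- 2 - r_oracle
    rho_model <- mean(equivol_to_chord(sf, rep(f, nrow(white$vertices))))
    expect_lt(abs(rho_model - rho_oracle), 0.02)
  }
})

test_that("equivolumetric closed form matches the analytic folded-cortex solution", {
  ph <- small_phantom()
  l12 <- ph$truth$layer12
  field <- compute_equivol_field(l12, ph$pair)
  truth_rho_sub <- ph$truth$layer4$depth_frac
  f_model <- chord_to_equivol(field, truth_rho_sub)
  # interior vertices (barycentric areas are biased on the open boundary)
  interior <- mean_curvature(ph$pair$white)$mask
  dev <- abs(f_model - ph$truth$layer4_equivol_sub)[interior]
  expect_lt(mean(dev), 0.02)
})

test_that("rasterized equivolumetric depth spans 0 at the upper surface to 1 at white", {
  ph <- small_phantom()
  field <- compute_equivol_field(ph$truth$layer12, ph$pair)
  ev <- equivol_volume(field, ph$volume)
  vals <- ev$data[!is.na(ev$data)]
  expect_gte(min(vals), 0)
  expect_lte(max(vals), 1)
  # the voxel containing a white vertex carries depth near 1
  vx <- round(world_to_voxel(ev, ph$pair$white$vertices[200, , drop = FALSE]))
  expect_gte(ev$data[vx], 0.85)
})

test_that("on-surface scalar smoothing is calibrated, mask-aware and identity at 0", {
  gm <- grid_mesh(41, 41, spacing = 0.5)
  x <- numeric(41 * 41)
  ctr <- 21 * 41 - 20
  x[ctr] <- 1
  expect_identical(smooth_scalar_on_surface(x, gm, 0), x)
  const <- rep(2.5, 41 * 41)
  expect_equal(smooth_scalar_on_surface(const, gm, 4), const, tolerance = 1e-12)
  # delta impulse vs planar Gaussian of the requested FWHM
  y <- smooth_scalar_on_surface(x, gm, 3)
  ctr_xy <- gm$vertices[ctr, 1:2]
  r2 <- rowSums(sweep(gm$vertices[, 1:2], 2, ctr_xy)^2)
  sig <- 3 / (2 * sqrt(2 * log(2)))
  ref <- exp(-r2 / (2 * sig^2)); ref <- ref / sum(ref)
  core <- sqrt(r2) < 8
  expect_lte(sqrt(mean((y[core] - ref[core])^2)) / max(ref), 0.1)
  # masked vertices neither emit nor receive
  mask <- rep(TRUE, 41 * 41); mask[ctr + 5] <- FALSE
  x2 <- x; x2[ctr + 5] <- 100
  y2 <- smooth_scalar_on_surface(x2, gm, 3, mask = mask)
  expect_equal(y2[ctr + 5], 100)   # did not receive
  expect_lte(max(abs(y2[mask] - y[mask])), 0.05 * max(ref))  # did not emit
})

test_that("Taubin smoothing preserves planes and sphere volume, unlike plain Laplacian", {
  # deep-interior vertices of a planar mesh have zero umbrella Laplacian;
  # boundary shrink propagates one ring per half-step, so keep clear of it
  gm <- grid_mesh(15, 15, spacing = 1)
  sm <- taubin_smooth(gm, 2)
  deep <- which(gm$vertices[, 1] >= 5 & gm$vertices[, 1] <= 9 &
                gm$vertices[, 2] >= 5 & gm$vertices[, 2] <= 9)
  expect_lt(max(abs(sm$vertices[deep, ] - gm$vertices[deep, ])), 1e-6)
  sp <- icosphere(3, 1)
  t50 <- taubin_smooth(sp, 50)
  expect_lt(abs(mean(sqrt(rowSums(t50$vertices^2))) - 1), 0.01)
  shrunk <- taubin_smooth(sp, 50, lambda = 0.33, mu = 0)  # plain Laplacian
  expect_lt(mean(sqrt(rowSums(shrunk$vertices^2))), 0.9)
  # noisy sphere: RMS radial deviation strictly decreases
  set.seed(31)
  noisy <- sp
  rad <- 1 + rnorm(nrow(sp$vertices), sd = 0.02)
  noisy$vertices <- sp$vertices * rad
  dn <- taubin_smooth(noisy, 20)
  rms <- function(m) sqrt(mean((sqrt(rowSums(m$vertices^2)) -
                                mean(sqrt(rowSums(m$vertices^2))))^2))
  expect_lt(rms(dn), rms(noisy))
})

test_that("layer IV initialization finds the peak after the upward inflection", {
  x <- seq(0, 1, length.out = 100)
  pair <- slab_pair(nx = 3, ny = 3, spacing = 0.4, z_top = 3, thickness = 2)
  upper <- layer_surface(rep(0, 9), pair$pial$vertices, pair$white$vertices,
                         pair$white$triangles, frame = "pial-white")
  mk <- function(prof) profile_set(matrix(rep(prof, 9), nrow = 9, byrow = TRUE),
                                   x, rep(2, 9), frame = "layer12-white")
  # dominant mid-depth peak at 0.5
  granular <- 60 + 35 * exp(-(x - 0.5)^2 / (2 * 0.06^2)) - 20 * x
  i4 <- init_layer4(mk(granular), upper, pair)
  expect_true(all(i4$resolved))
  expect_lte(max(abs(i4$depth_frac - 0.5)), 2 / 99)
  # monotone profile: unresolved
  mono <- init_layer4(mk(80 - 50 * x), upper, pair)
  expect_false(any(mono$resolved))
  # a sub-prominence first bump is skipped in favour of the second peak
  two <- 50 + 1.5 * exp(-(x - 0.35)^2 / (2 * 0.03^2)) +
    40 * exp(-(x - 0.6)^2 / (2 * 0.05^2)) + 10 * x
  i2 <- init_layer4(mk(two), upper, pair)
  expect_lte(max(abs(i2$depth_frac - 0.6)), 2 / 99)
})

test_that("an already-converged layer IV surface stops after one iteration", {
  ph <- small_phantom()
  det <- small_detection()
  l12 <- det$layer12
  psub <- resample_between_surfaces(small_phantom_smoothed(), l12, ph$pair)
  again <- refine_layer4(det$layer4, psub, ph$pair, l12)
  tr <- attr(again, "trace")
  expect_length(tr, 1)
  expect_equal(tr[1], 0)
  expect_equal(again$depth_frac, det$layer4$depth_frac, tolerance = 1 / 99)
})

test_that("layer IV is recovered at its equivolumetric depth across folds", {
  ph <- small_phantom()
  det <- small_detection()
  err_um <- abs(det$layer4$depth_frac_pial - ph$truth$layer4_depth_frac_pial) *
    pair_thickness(ph$pair) * 1000
  expect_lte(mean(err_um[det$layer4$mask]), 50)
  field <- compute_equivol_field(det$layer12, ph$pair)
  f4 <- chord_to_equivol(field, det$layer4$depth_frac)
  within <- abs(f4 - ph$truth$layer4_equivol_sub) <= 0.05
  expect_gte(mean(within[det$layer4$mask]), 0.95)
  expect_gte(cor(det$layer4$depth_frac, ph$truth$layer4$depth_frac), 0.9)
})

test_that("agranular patches are filled smoothly from the surround", {
  cfg <- small_phantom_config(agranular_x_range_mm = c(2.2, 3.4))
  ph <- generate_phantom(cfg)
  sm <- anisotropic_smooth(ph$volume, smoothing_config())
  det <- detect_layers(sm, ph$pair, ph$classification)
  expect_gt(det$qc$unresolved, 0)
  # no depth jump > 0.15 between neighbouring vertices
  e <- rbind(ph$pair$white$triangles[, 1:2], ph$pair$white$triangles[, 2:3],
             ph$pair$white$triangles[, c(3, 1)])
  jumps <- abs(det$layer4$depth_frac[e[, 1]] - det$layer4$depth_frac[e[, 2]])
  expect_lte(max(jumps), 0.15)
  # patch vertices sit near the surrounding equivolumetric depth
  field <- compute_equivol_field(det$layer12, ph$pair)
  f4 <- chord_to_equivol(field, det$layer4$depth_frac)
  patch <- ph$truth$agranular & det$layer4$mask
  expect_lt(mean(abs(f4[patch] - ph$truth$layer4_equivol_sub)), 0.07)
})

test_that("detection is deterministic and preserves laminar ordering", {
  ph <- small_phantom()
  sm <- small_phantom_smoothed()
  d1 <- detect_layers(sm, ph$pair, ph$classification)
  d2 <- detect_layers(sm, ph$pair, ph$classification)
  expect_identical(d1$layer12$depth_frac, d2$layer12$depth_frac)
  expect_identical(d1$layer4$depth_frac, d2$layer4$depth_frac)
  ok <- d1$layer12$mask & d1$layer4$mask
  expect_true(all(d1$layer12$depth_frac[ok] > 0))
  expect_true(all(d1$layer4$depth_frac_pial[ok] > d1$layer12$depth_frac[ok]))
  expect_true(all(d1$layer4$depth_frac_pial[ok] < 1))
  # convergence traces are monotone non-increasing on the phantom
  expect_true(all(diff(d1$qc$layer12_trace) <= 0))
  expect_true(all(diff(d1$qc$layer4_trace) <= 0))
})
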