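test_that("mean curvature matches analytic values on plane, sphere and cylinder", {
  gm <- grid_mesh(12, 12, spacing = 1)
  H <- mean_curvature(gm)
  expect_lt(max(abs(H$values[H$mask])), 1e-9)
  sp <- mean_curvature(icosphere(3, radius = 10))
  expect_lt(abs(mean(sp$values[sp$mask]) - 0.1) / 0.1, 0.03)
  expect_true(all(sp$values[sp$mask] > 0))   # outward-convex is positive
  cyl <- mean_curvature(cylinder_mesh(radius = 10))
  expect_lt(abs(mean(cyl$values[cyl$mask]) - 0.05) / 0.05, 0.05)
  # estimator converges with refinement
  err <- vapply(2:3, function(s) {
    h <- mean_curvature(icosphere(s, radius = 10))
    abs(mean(h$values[h$mask]) - 0.1)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("the mid-surface is the per-vertex chord midpoint", {
  pair <- slab_pair(nx = 5, ny = 5, spacing = 0.5, z_top = 2, thickness = 2)
  mid <- mid_surface(pair)
  expect_equal(unique(mid$vertices[, 3]), 1)
  same <- mid_surface(pair$white, pair$white)
  expect_equal(same$vertices, pair$white$vertices)
  ph <- small_phantom()
  pm <- mid_surface(ph$pair)
  # equals the analytic mid-fold surface within a voxel
  cur <- mean_curvature(pm)
  expect_equal(pm$vertices,
               (ph$pair$white$vertices + ph$pair$pial$vertices) / 2)
})

test_that("relative depth is the percentage position between layer I/II and white", {
  pair <- slab_pair(nx = 4, ny = 4, spacing = 0.5, z_top = 2, thickness = 2)
  nv <- 16
  l12 <- layer_surface(rep(0.1, nv), pair$pial$vertices, pair$white$vertices,
                       pair$white$triangles, frame = "pial-white")
  mk4 <- function(d) layer_surface(rep(d, nv), l12$coords,
                                   pair$white$vertices, pair$white$triangles,
                                   frame = "layer12-white")
  expect_equal(relative_depth(mk4(0.5), l12, pair)$values, rep(50, nv))
  expect_equal(relative_depth(mk4(1), l12, pair)$values, rep(100, nv))
  ph <- small_phantom()
  rd <- relative_depth(ph$truth$layer4, ph$truth$layer12, ph$pair)
  truth_rd <- 100 * ph$truth$layer4$depth_frac
  expect_lt(max(abs(rd$values - truth_rd)), 2)
})

test_that("vertex masking combines thickness and exclusion labels", {
  th <- c(2, 0.4, 3, 0.5, 1)
  expect_equal(mask_vertices(th), c(TRUE, FALSE, TRUE, TRUE, TRUE))
  excl <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  expect_equal(mask_vertices(th, excl), c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_true(all(mask_vertices(rep(2, 4))))
})

test_that("polynomial fits recover exact generators and nest in RSS", {
  set.seed(41)
  x <- runif(200, -1, 1)
  y <- 2 - 3 * x + 0.5 * x^2 + 4 * x^3
  fits <- fit_curvature_depth(x, y)
  expect_lt(fits$fits$order3$rss, 1e-12)
  expect_equal(unname(fits$fits$order3$coefficients),
               c(2, -3, 0.5, 4), tolerance = 1e-6)
  expect_equal(fits$selected, 3)
  yn <- y + rnorm(200, sd = 2)
  fn <- fit_curvature_depth(x, yn)
  expect_lte(fn$fits$order3$rss, fn$fits$order2$rss)
  expect_lte(fn$fits$order2$rss, fn$fits$order1$rss)
  expect_error(fit_curvature_depth(rep(1, 20), rnorm(20)), "rank")
  expect_error(fit_curvature_depth(x[1:5], y[1:5]), "10")
})

test_that("BIC selects the generating cubic in at least 90% of replicates", {
  set.seed(42)
  hits <- vapply(1:50, function(r) {
    x <- runif(10000, -0.5, 0.5)
    y <- 50 - 15 * x + 8 * x^2 + 40 * x^3 + rnorm(10000, sd = 5)
    fit_curvature_depth(x, y)$selected == 3
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("equivolumetric phantoms give a negative depth-curvature slope, equidistant none", {
  ph <- small_phantom()
  det <- small_detection()
  H <- mean_curvature(mid_surface(det$layer12, ph$pair$white))
  rd <- relative_depth(det$layer4, det$layer12, ph$pair)
  msk <- H$mask & rd$mask & mask_vertices(pair_thickness(ph$pair))
  Hs <- smooth_scalar_on_surface(H$values, ph$pair$white, 3, mask = msk)
  rs <- smooth_scalar_on_surface(rd$values, ph$pair$white, 3, mask = msk)
  fit <- fit_curvature_depth(Hs, rs, mask = msk)
  b_equi <- fit$fits$order1$coefficients[["beta1"]]
  expect_lt(b_equi, 0)
  # equidistant falsification phantom: slope indistinguishable from zero
  pe <- generate_phantom(small_phantom_config(), equidistant = TRUE)
  sme <- anisotropic_smooth(pe$volume, smoothing_config())
  dete <- detect_layers(sme, pe$pair, pe$classification)
  He <- mean_curvature(mid_surface(dete$layer12, pe$pair$white))
  rde <- relative_depth(dete$layer4, dete$layer12, pe$pair)
  mske <- He$mask & rde$mask
  Hse <- smooth_scalar_on_surface(He$values, pe$pair$white, 3, mask = mske)
  rse <- smooth_scalar_on_surface(rde$values, pe$pair$white, 3, mask = mske)
  fe <- fit_curvature_depth(Hse, rse, mask = mske)
  expect_lt(abs(fe$fits$order1$coefficients[["beta1"]]), abs(b_equi) / 10)
})

test_that("section angles follow the arcsin geometry", {
  pial <- grid_mesh(3, 3, spacing = 1, z = 1)
  mk <- function(dir) {
    w <- surface_mesh(sweep(pial$vertices, 2, dir, "+"), pial$triangles)
    surface_pair(white = w, pial = pial)
  }
  # chord in the section plane (N perpendicular to chord) -> 0 degrees
  a0 <- section_angle(mk(c(1, 0, 0)), c(0, 1, 0))
  expect_equal(a0$values, rep(0, 9))
  # chord parallel to N -> 90 degrees
  a90 <- section_angle(mk(c(0, 2, 0)), c(0, 1, 0))
  expect_equal(a90$values, rep(90, 9))
  a45 <- section_angle(mk(c(sqrt(2) / 2, sqrt(2) / 2, 0)), c(1, 0, 0))
  expect_equal(a45$values, rep(45, 9), tolerance = 1e-9)
  # invariant to endpoint swap and chord scaling
  p1 <- mk(c(0.3, 0.4, -0.2)); p2 <- mk(3 * c(0.3, 0.4, -0.2))
  swapped <- surface_pair(white = p1$pial, pial = p1$white)
  n <- c(0, 1, 0)
  expect_equal(section_angle(p1, n)$values, section_angle(swapped, n)$values)
  expect_equal(section_angle(p1, n)$values, section_angle(p2, n)$values,
               tolerance = 1e-9)
  expect_error(section_angle(p1, c(1, 1, 0)), "normal")
})

test_that("oblique-section overestimation is zero at 0, 100% at 60, convex increasing", {
  expect_equal(overestimation_error(0), 0)
  expect_equal(overestimation_error(60), 100, tolerance = 1e-9)
  expect_gte(overestimation_error(18), 5)
  a <- seq(0, 85, by = 5)
  e <- overestimation_error(a)
  expect_true(all(diff(e) > 0))          # strictly increasing
  expect_true(all(diff(diff(e)) > 0))    # convex
  expect_warning(bad <- overestimation_error(c(10, 95)), "90")
  expect_true(is.na(bad[2]))
})
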