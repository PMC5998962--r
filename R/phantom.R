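#' Synthetic folded-cortex phantom configuration
#'
#' The phantom emulates a cell-body-stained histological volume of folded
#' cortex with known laminar ground truth. The mid-surface is a sinusoidal
#' fold `z = z0 + A sin(2 pi x / lambda)` extruded along y; white and pial
#' surfaces are offset by half the cortical thickness along the analytic
#' normals; laminar bands are placed at constant *equivolumetric* depth, so
#' their chord-fraction depth varies with curvature by construction — the
#' geometric relationship the detection pipeline must recover.
#'
#' Defaults: 256 x 64 x 256 voxels at 40 um, thickness 2.5 mm, fold
#' wavelength 12 mm and amplitude 2 mm (safely inside the self-intersection
#' bound: the minimum radius of curvature `lambda^2 / (4 pi^2 A)` must
#' exceed half the thickness), six bands with layer IV brightest and layer
#' I dimmest, additive Gaussian noise of 5 intensity units.
#'
#' @param grid_dim volume dimensions (x, y, z).
#' @param voxel_size_um isotropic voxel size, um.
#' @param fold_amplitude_mm,fold_wavelength_mm sinusoid amplitude / period.
#' @param thickness_mm cortical thickness (constant along normals).
#' @param layer_fracs named equivolumetric volume fractions of layers
#'   I--VI (must sum to 1; pial to white order).
#' @param layer_levels staining-intensity level per layer (background 0;
#'   intensity increases with cell density: layer I dimmest, IV brightest).
#' @param white_level,background_level intensities outside the cortex.
#' @param agranular_x_range_mm optional c(lo, hi): x-interval of agranular
#'   cortex, in which the intensity of layers IV--VI decays monotonically
#'   from the layer III level toward the white level, so the profiles carry
#'   no granular peak.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param seed RNG seed for the noise.
#' @param mesh_nx,mesh_ny surface mesh grid resolution.
#' @param mesh_margin_mm margin between the mesh and the x/y volume edges.
#' @param section_y_mm y positions of generated manual-delineation
#'   sections (default: the mid-plane).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_dim = c(256, 64, 256), voxel_size_um = 40,
                           fold_amplitude_mm = 2, fold_wavelength_mm = 12,
                           thickness_mm = 2.5,
                           layer_fracs = c(I = 0.10, II = 0.10, III = 0.25,
                                           IV = 0.15, V = 0.20, VI = 0.20),
                           layer_levels = c(I = 20, II = 70, III = 50,
                                            IV = 95, V = 45, VI = 65),
                           white_level = 30, background_level = 0,
                           agranular_x_range_mm = NULL,
                           noise_sd = 5, seed = 1,
                           mesh_nx = 96, mesh_ny = 24, mesh_margin_mm = 0.4,
                           section_y_mm = NULL) {
  stopifnot(thickness_mm > 0, noise_sd >= 0,
            abs(sum(layer_fracs) - 1) < 1e-9, all(layer_fracs >= 0),
            length(layer_fracs) == length(layer_levels))
  if (fold_amplitude_mm > 0) {
    r_min <- fold_wavelength_mm^2 / (4 * pi^2 * fold_amplitude_mm)
    if (r_min <= thickness_mm / 2)
      stop(sprintf(
        paste0("self-intersecting folds: minimum radius of curvature ",
               "%.3f mm <= thickness/2 = %.3f mm ",
               "(need lambda^2 / (4 pi^2 A) > thickness / 2)"),
        r_min, thickness_mm / 2))
  }
  structure(as.list(environment()), class = "phantom_config")
}

# signed curvature of z(x) = z0 + A sin(2 pi x / lambda) wrt the pial-side
# normal (-z', 1)/sqrt(1 + z'^2); positive kappa shortens arcs toward pial
phantom_curve <- function(cfg, x) {
  om <- 2 * pi / cfg$fold_wavelength_mm
  A <- cfg$fold_amplitude_mm
  zp <- A * om * cos(om * x)
  zpp <- -A * om^2 * sin(om * x)
  den <- sqrt(1 + zp^2)
  list(z = A * sin(om * x),
       nx = -zp / den, nz = 1 / den,
       kappa = zpp / den^3)
}

# offset s (distance from mid-surface toward pial) enclosing equivolumetric
# fraction f below the pial surface: f*t = (t/2 - s) - kappa/2*(t^2/4 - s^2)
phantom_offset_for_f <- function(f, kappa, t) {
  c0 <- t / 2 - kappa * t^2 / 8 - f * t
  ifelse(abs(kappa) < 1e-12, c0, 2 * c0 / (1 + sqrt(pmax(1 - 2 * kappa * c0, 0))))
}

# equivolumetric fraction below pial at offset s
phantom_f_at_offset <- function(s, kappa, t) {
  ((t / 2 - s) - kappa / 2 * (t^2 / 4 - s^2)) / t
}

# agranular variant of the band levels: layers from IV down decay
# monotonically from the layer III level toward the white level, removing
# both the granular (IV) and the deep (VI) intensity peaks
agranular_levels <- function(layer_fracs, layer_levels, white_level) {
  iv <- which(names(layer_fracs) == "IV")
  if (length(iv) != 1 || iv <= 1) return(layer_levels)
  cum <- cumsum(layer_fracs)
  out <- layer_levels
  top <- layer_levels[iv - 1]
  f0 <- cum[iv - 1]
  for (b in iv:length(layer_fracs)) {
    mid <- cum[b] - layer_fracs[b] / 2
    out[b] <- top + (white_level - top) * (mid - f0) / (1 - f0)
  }
  out
}

#' Generate a folded-cortex phantom
#'
#' Produces, consistently from one configuration: the intensity volume
#' (laminar bands plus seeded Gaussian noise), the linked white/pial
#' surface pair, a tissue classification (background / layer I /
#' gray / white), the ground truth (true layer I/II and mid-layer IV
#' surfaces as chord fractions and equivolumetric depths, plus the
#' analytic mid-surface mean curvature), and manual delineations of the
#' requested sections. Identical seeds give bit-identical output.
#'
#' @param cfg a [phantom_config()].
#' @param equidistant if `TRUE`, laminar bands are placed at constant
#'   *chord* fraction instead of constant volume fraction — a
#'   falsification mode in which layer depth is unrelated to curvature.
#' @return list (class `phantom`) with `volume`, `pair`, `classification`,
#'   `truth`, `delineations`, `config`.
#' @export
generate_phantom <- function(cfg = phantom_config(), equidistant = FALSE) {
  stopifnot(inherits(cfg, "phantom_config"))
  vs <- cfg$voxel_size_um / 1000
  d <- cfg$grid_dim
  ext <- (d - 1) * vs
  z0 <- ext[3] / 2
  t <- cfg$thickness_mm
  gx <- (seq_len(d[1]) - 1) * vs
  gz <- (seq_len(d[3]) - 1) * vs
  # dense curve samples, extended past the grid so edge voxels find a foot
  xs <- seq(-2, ext[1] + 2, by = vs / 2)
  cur <- phantom_curve(cfg, xs)
  cz <- z0 + cur$z
  # nearest curve point per (x, z) grid location, chunked running argmin
  px <- rep(gx, times = d[3])
  pz <- rep(gz, each = d[1])
  np <- length(px)
  best <- rep(Inf, np); bestj <- rep(1L, np)
  chunk <- 128L
  for (lo in seq(1, length(xs), by = chunk)) {
    hi <- min(lo + chunk - 1L, length(xs))
    M <- outer(px, xs[lo:hi], "-")^2 + outer(pz, cz[lo:hi], "-")^2
    j <- max.col(-M, ties.method = "first")
    v <- M[cbind(seq_len(np), j)]
    upd <- v < best
    best[upd] <- v[upd]
    bestj[upd] <- j[upd] + lo - 1L
  }
  nx_f <- cur$nx[bestj]; nz_f <- cur$nz[bestj]
  s <- sqrt(best) * sign((px - xs[bestj]) * nx_f + (pz - cz[bestj]) * nz_f)
  kap <- if (equidistant) rep(0, np) else cur$kappa[bestj]
  f <- phantom_f_at_offset(s, kap, t)
  cum <- cumsum(cfg$layer_fracs)
  nl <- length(cum)
  band <- findInterval(pmin(pmax(f, 0), 1 - 1e-12), c(0, cum),
                       rightmost.closed = TRUE, all.inside = TRUE)
  levels2d <- cfg$layer_levels[band]
  agr <- rep(FALSE, np)
  if (!is.null(cfg$agranular_x_range_mm)) {
    xr <- cfg$agranular_x_range_mm
    agr <- xs[bestj] >= xr[1] & xs[bestj] <= xr[2]
    alev <- agranular_levels(cfg$layer_fracs, cfg$layer_levels,
                             cfg$white_level)
    for (b in which(alev != cfg$layer_levels))
      levels2d[agr & band == b] <- alev[b]
  }
  in_cortex <- abs(s) <= t / 2
  levels2d[!in_cortex & s > 0] <- cfg$background_level
  levels2d[!in_cortex & s < 0] <- cfg$white_level
  lab2d <- integer(np)
  lab2d[in_cortex & band == 1L] <- 1L
  lab2d[in_cortex & band > 1L] <- 2L
  lab2d[!in_cortex & s < 0] <- 3L
  to3d <- function(m2d) {
    a <- array(m2d, dim = c(d[1], d[3], d[2]))
    aperm(a, c(1, 3, 2))
  }
  set.seed(cfg$seed)
  intensity <- to3d(levels2d) + stats::rnorm(prod(d), sd = cfg$noise_sd)
  vol <- intensity_volume(intensity, cfg$voxel_size_um)
  cls <- tissue_classification(to3d(lab2d), cfg$voxel_size_um)

  # surface pair on a regular (x, y) grid; the x-margin accounts for the
  # maximum in-plane tilt of the offset normals so chord endpoints stay
  # inside the volume
  om <- 2 * pi / cfg$fold_wavelength_mm
  slope_max <- cfg$fold_amplitude_mm * om
  nx_max <- slope_max / sqrt(1 + slope_max^2)
  m <- cfg$mesh_margin_mm + t / 2 * nx_max
  if (ext[3] < 2 * cfg$fold_amplitude_mm + t + 2 * vs)
    stop("grid too small in z for the folds plus cortex")
  xm <- seq(m, ext[1] - m, length.out = cfg$mesh_nx)
  ym <- seq(cfg$mesh_margin_mm, ext[2] - cfg$mesh_margin_mm,
            length.out = cfg$mesh_ny)
  cm <- phantom_curve(cfg, xm)
  nv <- cfg$mesh_nx * cfg$mesh_ny
  X <- rep(xm, times = cfg$mesh_ny)
  Y <- rep(ym, each = cfg$mesh_nx)
  Zc <- rep(z0 + cm$z, times = cfg$mesh_ny)
  NXv <- rep(cm$nx, times = cfg$mesh_ny)
  NZv <- rep(cm$nz, times = cfg$mesh_ny)
  offset_pt <- function(sv) cbind(X + sv * NXv, Y, Zc + sv * NZv)
  pial_v <- offset_pt(rep(t / 2, nv))
  white_v <- offset_pt(rep(-t / 2, nv))
  tri <- NULL
  idx <- function(i, j) (j - 1L) * cfg$mesh_nx + i
  i <- rep(seq_len(cfg$mesh_nx - 1L), times = cfg$mesh_ny - 1L)
  j <- rep(seq_len(cfg$mesh_ny - 1L), each = cfg$mesh_nx - 1L)
  tri <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
               cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  pair <- surface_pair(white = surface_mesh(white_v, tri),
                       pial = surface_mesh(pial_v, tri))

  kv_true <- rep(cm$kappa, times = cfg$mesh_ny)
  kv <- if (equidistant) rep(0, nv) else kv_true
  f12 <- cum[1]
  ivi <- which(names(cfg$layer_fracs) == "IV")
  f4 <- cum[ivi - 1] + cfg$layer_fracs[ivi] / 2
  s12 <- phantom_offset_for_f(f12, kv, t)
  s4 <- phantom_offset_for_f(f4, kv, t)
  rho12 <- (t / 2 - s12) / t           # chord fraction from pial
  rho4 <- (t / 2 - s4) / t
  agr_v <- rep(FALSE, nv)
  if (!is.null(cfg$agranular_x_range_mm))
    agr_v <- X >= cfg$agranular_x_range_mm[1] &
      X <= cfg$agranular_x_range_mm[2]
  truth <- list(
    layer12 = layer_surface(rho12, pial_v, white_v, tri,
                            frame = "pial-white"),
    layer4 = layer_surface((rho4 - rho12) / (1 - rho12),
                           offset_pt(s12), white_v, tri,
                           frame = "layer12-white"),
    layer4_depth_frac_pial = rho4,
    layer4_equivol_sub = unname((f4 - f12) / (1 - f12)),
    curvature = vertex_scalar_map(-kv_true / 2, units = "mm^-1"),
    agranular = agr_v,
    thickness_mm = t)

  ym_margin <- cfg$mesh_margin_mm
  secs <- cfg$section_y_mm
  if (is.null(secs)) secs <- ext[2] / 2
  xd <- seq(m, ext[1] - m, by = vs)
  cd <- phantom_curve(cfg, xd)
  kd <- if (equidistant) rep(0, length(xd)) else cd$kappa
  poly_at <- function(sv) cbind(xd + sv * cd$nx, z0 + cd$z + sv * cd$nz)
  f4u <- cum[ivi - 1]; f4l <- cum[ivi]
  delineations <- lapply(seq_along(secs), function(si)
    manual_delineation(
      sample_id = sprintf("phantom_y%.2f", secs[si]),
      axis = "y", coord = secs[si],
      polylines = list(
        pial = poly_at(rep(t / 2, length(xd))),
        layer12 = poly_at(phantom_offset_for_f(f12, kd, t)),
        layer4_upper = poly_at(phantom_offset_for_f(f4u, kd, t)),
        layer4_lower = poly_at(phantom_offset_for_f(f4l, kd, t)),
        white = poly_at(rep(-t / 2, length(xd))))))

  structure(list(volume = vol, pair = pair, classification = cls,
                 truth = truth, delineations = delineations, config = cfg),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  d <- x$config$grid_dim
  cat(sprintf(
    "<phantom> %dx%dx%d @ %g um; A = %g mm, lambda = %g mm, t = %g mm; %d mesh vertices\n",
    d[1], d[2], d[3], x$config$voxel_size_um, x$config$fold_amplitude_mm,
    x$config$fold_wavelength_mm, x$config$thickness_mm,
    nrow(x$pair$white$vertices)))
  invisible(x)
}

#' Analytic 1D laminar profiles with seeded noise
#'
#' Flat-geometry laminar profiles: piecewise-constant band levels against
#' fractional depth plus additive Gaussian noise; the 1D fixture for
#' smoothing-level selection and peak-count analyses.
#'
#' @param n samples per profile (default 100).
#' @param m number of profiles.
#' @param layer_fracs,layer_levels band geometry and levels (defaults as
#'   in [phantom_config()]).
#' @param agranular if `TRUE`, layers IV--VI decay monotonically from the
#'   layer III level toward the white level (no granular peak).
#' @param white_tail_frac fraction of the deep end of the profile taking
#'   the white-matter level, emulating the partial-volume blend at the
#'   gray/white boundary seen in volume-sampled profiles (default 0.04).
#' @param white_level white-matter intensity for the tail.
#' @param noise_sd,seed noise model.
#' @return m x n matrix of profiles (one per row).
#' @export
phantom_profile <- function(n = 100, m = 1,
                            layer_fracs = c(I = 0.10, II = 0.10, III = 0.25,
                                            IV = 0.15, V = 0.20, VI = 0.20),
                            layer_levels = c(I = 20, II = 70, III = 50,
                                             IV = 95, V = 45, VI = 65),
                            agranular = FALSE, white_tail_frac = 0.04,
                            white_level = 30, noise_sd = 5, seed = 1) {
  stopifnot(abs(sum(layer_fracs) - 1) < 1e-9)
  levels <- if (agranular)
    agranular_levels(layer_fracs, layer_levels, white_level)
  else layer_levels
  depth <- seq(0, 1, length.out = n)
  band <- findInterval(pmin(depth, 1 - 1e-12),
                       c(0, cumsum(layer_fracs) * (1 - white_tail_frac), 1),
                       rightmost.closed = TRUE, all.inside = TRUE)
  base <- c(levels, white_level)[band]
  set.seed(seed)
  matrix(rep(base, each = m), nrow = m) +
    matrix(stats::rnorm(m * n, sd = noise_sd), nrow = m)
}
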