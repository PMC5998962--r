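#' Layer-detection configuration
#'
#' Parameters of the iterative laminar surface detection.
#'
#' @param layer1_fallback_depth_um initial layer I/II depth below the pial
#'   surface when no tissue classification is available (or no layer I/gray
#'   transition is found); default 200 um.
#' @param layer1_max_depth_um maximum plausible depth of the layer I/II
#'   boundary used to reject intensity-matched positions during refinement;
#'   default 200 um (the expected thickness of layer I).
#' @param neighbor_smooth_iters iterations of nearest-neighbour averaging of
#'   boundary intensity values on the surface; default 3.
#' @param equivol_smooth_fwhm_mm FWHM of the on-surface Gaussian smoothing
#'   of equivolumetric depth during layer IV refinement; default 10 mm.
#' @param convergence_max_moved_frac convergence rule: stop when fewer than
#'   this fraction of vertices changed location (by more than one profile
#'   sample step) between successive iterations. Default 100/163842,
#'   expressed as a fraction so the rule scales to meshes of any size.
#' @param peak_prominence_frac prominence a profile peak must reach, as a
#'   fraction of the profile range, to qualify as the "large" layer IV
#'   peak; default 0.15. True laminar peaks reach prominences well above a
#'   quarter of the range, while residual noise bumps in low-contrast
#'   (agranular) profiles stay below ~10%, so this cleanly separates the
#'   two; it is deliberately stricter than the 5% used for peak *counting*
#'   during smoothing-level selection.
#' @param max_iterations cap on refinement iterations; default 20.
#' @param taubin_iters_per_pass Taubin mesh-smoothing iterations applied in
#'   each layer IV refinement pass; default 5.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(layer1_fallback_depth_um = 200,
                             layer1_max_depth_um = 200,
                             neighbor_smooth_iters = 3,
                             equivol_smooth_fwhm_mm = 10,
                             convergence_max_moved_frac = 100 / 163842,
                             peak_prominence_frac = 0.15,
                             max_iterations = 20,
                             taubin_iters_per_pass = 5) {
  stopifnot(layer1_fallback_depth_um > 0, layer1_max_depth_um > 0,
            neighbor_smooth_iters >= 0, equivol_smooth_fwhm_mm >= 0,
            convergence_max_moved_frac > 0, convergence_max_moved_frac < 1,
            peak_prominence_frac >= 0, max_iterations >= 1)
  structure(as.list(environment()), class = "detection_config")
}

#' Intracortical layer surface
#'
#' A detected laminar surface expressed as a per-vertex fractional depth on
#' the chord between an upper reference surface (pial or layer I/II) and
#' the white surface, plus the corresponding 3D coordinates
#' `upper + depth_frac * (white - upper)`.
#'
#' @param depth_frac per-vertex fractional depth in `[0, 1]` (0 = upper
#'   reference surface, 1 = white).
#' @param upper_coords,lower_coords n x 3 chord endpoint coordinates (mm).
#' @param triangles shared mesh topology.
#' @param mask logical validity mask.
#' @param frame `"pial-white"` or `"layer12-white"`.
#' @param resolved optional logical: vertices whose position came from a
#'   detected profile feature (as opposed to neighbourhood interpolation).
#' @return An object of class `layer_surface`.
#' @export
layer_surface <- function(depth_frac, upper_coords, lower_coords, triangles,
                          mask = NULL, frame = "pial-white",
                          resolved = NULL) {
  nv <- nrow(upper_coords)
  if (is.null(mask)) mask <- rep(TRUE, nv)
  if (is.null(resolved)) resolved <- mask
  depth_frac <- pmin(pmax(as.numeric(depth_frac), 0), 1)
  coords <- upper_coords + depth_frac * (lower_coords - upper_coords)
  structure(list(depth_frac = depth_frac, coords = coords,
                 upper_coords = upper_coords, lower_coords = lower_coords,
                 triangles = triangles, mask = as.logical(mask),
                 frame = frame, resolved = as.logical(resolved)),
            class = "layer_surface")
}

#' @export
print.layer_surface <- function(x, ...) {
  d <- x$depth_frac[x$mask]
  cat(sprintf(
    "<layer_surface> [%s] %d vertices (%d valid, %d resolved); depth %.3f (sd %.3f)\n",
    x$frame, length(x$depth_frac), sum(x$mask), sum(x$resolved),
    mean(d), stats::sd(d)))
  invisible(x)
}

#' Extract the mesh of a layer surface
#'
#' @param surface a [layer_surface()].
#' @return A [surface_mesh()] at the layer coordinates.
#' @export
layer_mesh <- function(surface) {
  surface_mesh(surface$coords, surface$triangles)
}

# linear interpolation of one profile at fractional depth x (0..1)
interp_profile <- function(samples, x) {
  n <- length(samples)
  pos <- x * (n - 1) + 1
  i <- pmin(pmax(floor(pos), 1), n - 1)
  fr <- pos - i
  samples[i] * (1 - fr) + samples[i + 1] * fr
}

# neighbor-mean of x over valid entries; keeps x where no valid neighbor
neighbor_mean <- function(x, adj, valid = NULL) {
  if (is.null(valid)) valid <- rep(TRUE, length(x))
  xv <- ifelse(valid, x, 0)
  num <- as.numeric(adj %*% xv)
  den <- as.numeric(adj %*% as.numeric(valid))
  out <- x
  ok <- den > 0
  out[ok] <- num[ok] / den[ok]
  out
}

#' Initialize the layer I/II boundary surface
#'
#' Places the boundary, per vertex, at the first transition from the layer I
#' label to the gray (layers II--VI) label along the profile, walking from
#' the pial end. Where no such transition exists — or when no tissue
#' classification is supplied — the boundary is placed
#' `layer1_fallback_depth_um` below the pial surface. Vertices thinner than
#' the fallback depth are masked.
#'
#' @param profiles a [profile_set()] in the `"pial-white"` frame.
#' @param pair the [surface_pair()] the profiles were extracted from.
#' @param cls optional [tissue_classification()] on a compatible grid.
#' @param cfg a [detection_config()].
#' @return A [layer_surface()] in the `"pial-white"` frame.
#' @export
init_layer12 <- function(profiles, pair, cls = NULL,
                         cfg = detection_config()) {
  stopifnot(inherits(profiles, "profile_set"),
            identical(profiles$frame, "pial-white"))
  n <- profiles$n
  thick <- pair_thickness(pair)
  nv <- nrow(pair$white$vertices)
  fall_mm <- cfg$layer1_fallback_depth_um / 1000
  mask <- profiles$mask & (thick >= fall_mm)
  depth <- fall_mm / pmax(thick, 1e-9)
  from_labels <- rep(FALSE, nv)
  if (!is.null(cls)) {
    pp <- profile_points(pair$pial$vertices, pair$white$vertices, n)
    lab <- matrix(sample_labels(cls, pp$points), nrow = nv, ncol = n,
                  byrow = TRUE)
    l1 <- cls$codebook[["layer1"]]; gr <- cls$codebook[["gray"]]
    trans <- lab[, 1:(n - 1), drop = FALSE] == l1 &
      lab[, 2:n, drop = FALSE] == gr
    has <- rowSums(trans, na.rm = TRUE) > 0
    trans[is.na(trans)] <- FALSE
    first <- max.col(trans, ties.method = "first")
    depth[has] <- (first[has] - 0.5) / (n - 1)
    from_labels <- has
  }
  depth[!mask] <- NA_real_
  depth[is.na(depth)] <- 0
  layer_surface(depth, pair$pial$vertices, pair$white$vertices,
                pair$white$triangles, mask = mask, frame = "pial-white",
                resolved = from_labels & mask)
}

# interior local maxima indices of a vector (strict)
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer())
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
}

# depths (fractional) where the piecewise-linear profile equals value
profile_matches <- function(samples, value) {
  n <- length(samples)
  d <- samples - value
  out <- numeric()
  eq <- which(abs(d) < 1e-12)
  if (length(eq)) out <- (eq - 1) / (n - 1)
  cross <- which(d[-n] * d[-1] < 0)
  if (length(cross)) {
    fr <- d[cross] / (d[cross] - d[cross + 1])
    out <- c(out, (cross - 1 + fr) / (n - 1))
  }
  sort(out)
}

# nearest candidate to x; ties broken toward the smaller (pial) value
nearest_candidate <- function(cands, x, tol = 1e-9) {
  dd <- abs(cands - x)
  sel <- which(dd <= min(dd) + tol)
  min(cands[sel])
}

#' Refine the layer I/II boundary surface
#'
#' Iterates two corrections until convergence: (1) *gradient adjustment* —
#' each vertex moves to the closest local maximum of the profile's first
#' derivative (the inflection marking the sharp rise in cell density from
#' layer I into layer II; ties broken toward the pial side); (2) *intensity
#' matching after on-surface smoothing* — the boundary intensity values are
#' smoothed across the surface by `neighbor_smooth_iters` iterations of
#' nearest-neighbour averaging, and each vertex moves to the profile
#' position nearest in depth whose interpolated intensity matches its
#' smoothed value. Vertices with no matching value, or whose matched
#' position lies deeper than `layer1_max_depth_um` below the pial surface,
#' are set to the average depth of their mesh neighbours instead.
#'
#' Iteration stops when the fraction of vertices that moved by more than
#' one profile sample step falls below `convergence_max_moved_frac`, or at
#' `max_iterations` (with a warning reporting the moved-vertex count).
#'
#' @param surface the initialized [layer_surface()] (see [init_layer12()]).
#' @param profiles the [profile_set()] in the `"pial-white"` frame.
#' @param pair the [surface_pair()].
#' @param cfg a [detection_config()].
#' @return The refined [layer_surface()]; the per-iteration moved-vertex
#'   counts are in attribute `"trace"`.
#' @export
refine_layer12 <- function(surface, profiles, pair,
                           cfg = detection_config()) {
  stopifnot(inherits(surface, "layer_surface"),
            identical(surface$frame, "pial-white"))
  n <- profiles$n
  h <- 1 / (n - 1)
  nv <- length(surface$depth_frac)
  mask <- surface$mask & profiles$mask
  thick <- pair_thickness(pair)
  adj <- mesh_adjacency(pair$white)
  grad <- profile_gradient(profiles)
  gmax <- lapply(seq_len(nv), function(v)
    if (mask[v]) (local_maxima(grad[v, ]) - 1) * h else numeric())
  depth <- surface$depth_frac
  max_frac <- cfg$layer1_max_depth_um / 1000 / pmax(thick, 1e-9)
  trace <- integer()
  for (it in seq_len(cfg$max_iterations)) {
    prev <- depth
    # step 1: move to the closest maximum gradient (inflection point)
    for (v in which(mask)) {
      if (length(gmax[[v]]))
        depth[v] <- nearest_candidate(gmax[[v]], depth[v])
    }
    # step 2: smooth boundary intensities on the surface, re-match by value
    val <- vapply(seq_len(nv), function(v)
      if (mask[v]) interp_profile(profiles$samples[v, ], depth[v])
      else NA_real_, numeric(1))
    sval <- val
    for (s in seq_len(cfg$neighbor_smooth_iters))
      sval <- neighbor_mean(sval, adj, valid = mask & !is.na(sval))
    cand <- depth
    bad <- rep(FALSE, nv)
    for (v in which(mask)) {
      m <- profile_matches(profiles$samples[v, ], sval[v])
      if (!length(m)) { bad[v] <- TRUE; next }
      dv <- nearest_candidate(m, depth[v])
      if (dv > max_frac[v]) bad[v] <- TRUE else cand[v] <- dv
    }
    nb <- neighbor_mean(cand, adj, valid = mask & !bad)
    depth <- ifelse(bad, nb, cand)
    moved <- sum(abs(depth - prev) > h & mask)
    trace <- c(trace, moved)
    if (moved / max(1, sum(mask)) < cfg$convergence_max_moved_frac) break
    if (it == cfg$max_iterations)
      warning(sprintf(
        "layer I/II refinement not converged after %d iterations (%d vertices still moving)",
        it, moved))
  }
  out <- layer_surface(depth, surface$upper_coords, surface$lower_coords,
                       surface$triangles, mask = mask, frame = "pial-white",
                       resolved = mask)
  attr(out, "trace") <- trace
  out
}

# ---- equivolumetric depth -------------------------------------------------

#' Equivolumetric depth field between an upper surface and the white surface
#'
#' The equivolumetric model places a layer at a constant *volume* fraction
#' of the cortex rather than a constant distance fraction, which makes
#' layers relatively deeper (by chord fraction) in sulcal fundi and
#' shallower on gyral crowns. Around each linked vertex pair the cortex is
#' modelled as a truncated prism whose cross-sectional area interpolates
#' linearly from the local upper-surface area `A_up` to the local
#' white-surface area `A_w`; the surface enclosing volume fraction `f`
#' above it then sits at chord fraction `rho` solving
#' `(A_w - A_up)/2 * rho^2 + A_up * rho = f * (A_up + A_w)/2`,
#' which reduces to `rho = f` when `A_up = A_w`. Local areas are the
#' per-vertex barycentric areas ([vertex_areas()]). Vertices with zero
#' local area are masked.
#'
#' @param upper a [layer_surface()] (or n x 3 coordinate matrix) forming the
#'   upper boundary; typically the layer I/II surface or the pial surface.
#' @param pair the [surface_pair()] supplying the white surface and topology.
#' @return An object of class `equivol_field` with fields `A_upper`,
#'   `A_white` and `mask`; use [chord_to_equivol()] / [equivol_to_chord()]
#'   to convert per-vertex depths, and [equivol_volume()] to rasterize the
#'   field into a voxel grid.
#' @export
compute_equivol_field <- function(upper, pair) {
  up <- if (inherits(upper, "layer_surface")) upper$coords else as_points(upper)
  A_up <- vertex_areas(surface_mesh(up, pair$white$triangles))
  A_w <- vertex_areas(pair$white)
  mask <- A_up > 0 & A_w > 0
  structure(list(A_upper = A_up, A_white = A_w, mask = mask,
                 upper_coords = up, white_coords = pair$white$vertices),
            class = "equivol_field")
}

#' Convert per-vertex chord fraction to equivolumetric depth (and back)
#'
#' @param field an `equivol_field` from [compute_equivol_field()].
#' @param rho per-vertex chord fraction in `[0, 1]` (0 = upper surface).
#' @return per-vertex fractional depth (masked vertices return the linear
#'   fraction unchanged).
#' @export
chord_to_equivol <- function(field, rho) {
  stopifnot(inherits(field, "equivol_field"))
  au <- field$A_upper; aw <- field$A_white
  f <- (au * rho + (aw - au) * rho^2 / 2) / ((au + aw) / 2)
  ifelse(field$mask, f, rho)
}

#' @rdname chord_to_equivol
#' @param f per-vertex equivolumetric depth in `[0, 1]`.
#' @export
equivol_to_chord <- function(field, f) {
  stopifnot(inherits(field, "equivol_field"))
  au <- field$A_upper; aw <- field$A_white
  d <- aw - au
  lin <- abs(d) < 1e-9 * (au + aw + 1e-300)
  rho <- f
  i <- field$mask & !lin
  rho[i] <- (-au[i] + sqrt(pmax((1 - f[i]) * au[i]^2 + f[i] * aw[i]^2, 0))) /
    d[i]
  pmin(pmax(rho, 0), 1)
}

#' Rasterize equivolumetric depth into a voxel grid
#'
#' Samples each vertex chord at regular steps, evaluates the per-vertex
#' equivolumetric depth at each chord fraction, and averages the values of
#' all chord samples falling into each voxel. Voxels traversed by no chord
#' are `NA`.
#'
#' @param field an `equivol_field`.
#' @param template an [intensity_volume()] supplying the target grid.
#' @param steps samples per chord (default 4 per voxel of mean thickness).
#' @return An [intensity_volume()] of fractional depths (`NA` outside).
#' @export
equivol_volume <- function(field, template, steps = NULL) {
  stopifnot(inherits(field, "equivol_field"),
            inherits(template, "intensity_volume"))
  d <- dim(template$data)
  up <- field$upper_coords; wh <- field$white_coords
  if (is.null(steps)) {
    thick <- sqrt(rowSums((wh - up)^2))
    steps <- max(8L, ceiling(4 * mean(thick) * 1000 / template$voxel_size_um))
  }
  t <- seq(0, 1, length.out = steps)
  nv <- nrow(up)
  rho <- rep(t, times = nv)
  vidx <- rep(seq_len(nv), each = steps)
  au <- field$A_upper[vidx]; aw <- field$A_white[vidx]
  f <- ifelse(field$mask[vidx],
              (au * rho + (aw - au) * rho^2 / 2) / ((au + aw) / 2),
              rho)
  # positions of each chord sample
  pts <- up[vidx, , drop = FALSE] +
    rho * (wh[vidx, , drop = FALSE] - up[vidx, , drop = FALSE])
  vox <- round(world_to_voxel(template, pts))
  ok <- vox[, 1] >= 1 & vox[, 1] <= d[1] & vox[, 2] >= 1 & vox[, 2] <= d[2] &
    vox[, 3] >= 1 & vox[, 3] <= d[3] & field$mask[vidx]
  lin <- (vox[ok, 3] - 1) * d[1] * d[2] + (vox[ok, 2] - 1) * d[1] + vox[ok, 1]
  sums <- rowsum(f[ok], lin)
  cnts <- rowsum(rep(1, sum(ok)), lin)
  out <- array(NA_real_, d)
  out[as.integer(rownames(sums))] <- sums[, 1] / cnts[, 1]
  intensity_volume(out, template$voxel_size_um, template$origin_mm)
}

# ---- on-surface scalar smoothing and mesh smoothing -----------------------

#' Smooth a per-vertex scalar map across the surface
#'
#' Geodesic heat-kernel smoothing by iterated neighbour diffusion,
#' calibrated so that the accumulated kernel matches the requested FWHM on
#' the mesh: each iteration applies `x <- (1 - w) x + w * mean(neighbours)`,
#' which adds per-axis kernel variance `w * mean(|edge|^2) / 2`, so the
#' number of iterations and the weight are chosen to satisfy
#' `FWHM^2 = 8 ln 2 * N * w * mean(|edge|^2) / 2`. `fwhm_mm = 0` is the
#' identity and constant maps are unchanged. Masked vertices neither emit
#' nor receive weight; disconnected vertices are left unchanged with a
#' warning.
#'
#' @param map a [vertex_scalar_map()] or numeric vector.
#' @param mesh the [surface_mesh()] carrying the map.
#' @param fwhm_mm kernel FWHM in mm.
#' @param mask optional validity override.
#' @return Object of the same type as `map`, smoothed.
#' @export
smooth_scalar_on_surface <- function(map, mesh, fwhm_mm, mask = NULL) {
  is_map <- inherits(map, "vertex_scalar_map")
  x <- if (is_map) map$values else as.numeric(map)
  if (is.null(mask)) mask <- if (is_map) map$mask else rep(TRUE, length(x))
  if (length(x) != nrow(mesh$vertices)) stop("map not aligned to mesh")
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(map)
  e <- mesh_edges(mesh)
  keep <- mask[e[, 1]] & mask[e[, 2]]
  e <- e[keep, , drop = FALSE]
  ev <- mesh$vertices[e[, 1], , drop = FALSE] -
    mesh$vertices[e[, 2], , drop = FALSE]
  m2 <- mean(rowSums(ev^2))
  nvert <- length(x)
  adj <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                              x = 1, dims = c(nvert, nvert))
  deg <- as.numeric(adj %*% rep(1, nvert))
  if (any(mask & deg == 0))
    warning("disconnected vertices left unchanged")
  w_max <- 0.8
  niter <- max(1L, ceiling(fwhm_mm^2 / (4 * log(2) * w_max * m2)))
  w <- fwhm_mm^2 / (4 * log(2) * niter * m2)
  y <- x
  act <- mask & deg > 0
  for (i in seq_len(niter)) {
    nb <- as.numeric(adj %*% y) / pmax(deg, 1)
    y[act] <- (1 - w) * y[act] + w * nb[act]
  }
  if (is_map) vertex_scalar_map(y, units = map$units, mask = mask) else y
}

#' Taubin mesh smoothing without shrinkage
#'
#' Alternating lambda/mu umbrella-Laplacian steps: a positive smoothing
#' step (`lambda`) followed by a slightly larger negative step (`mu`),
#' which removes high-curvature kinks without the volume shrinkage of plain
#' Laplacian smoothing. Topology is unchanged.
#'
#' @param mesh a [surface_mesh()].
#' @param iterations number of lambda/mu passes.
#' @param lambda,mu step sizes (defaults 0.33 / -0.34).
#' @return The smoothed [surface_mesh()].
#' @export
taubin_smooth <- function(mesh, iterations = 10, lambda = 0.33, mu = -0.34) {
  stopifnot(inherits(mesh, "surface_mesh"), iterations >= 0)
  if (iterations == 0) return(mesh)
  adj <- mesh_adjacency(mesh)
  deg <- pmax(as.numeric(adj %*% rep(1, nrow(mesh$vertices))), 1)
  v <- mesh$vertices
  for (i in seq_len(iterations)) {
    v <- v + lambda * (as.matrix(adj %*% v) / deg - v)
    v <- v + mu * (as.matrix(adj %*% v) / deg - v)
  }
  surface_mesh(v, mesh$triangles)
}

# ---- layer IV -------------------------------------------------------------

# qualifying peak depths (fractional) for one sub-profile
layer4_peak_depths <- function(samples, prominence_frac) {
  n <- length(samples)
  rng <- diff(range(samples))
  if (rng == 0) return(numeric())
  pk <- profile_peaks(samples)
  keep <- pk$prominence >= prominence_frac * rng
  (pk$idx[keep] - 1) / (n - 1)
}

#' Initialize the mid-layer IV surface
#'
#' On profiles resampled between the layer I/II boundary and the white
#' surface, layer IV appears as a large intensity peak that follows an
#' upward inflection marking layer II/III (layer II is often, but not
#' always, itself a peak, so the upward inflection is the more reliable
#' marker). Per vertex this takes the first interior profile peak — with
#' prominence at least `peak_prominence_frac` of the profile range —
#' occurring after the first point where both the first and the second
#' profile derivatives are positive (an accelerating rise). Vertices with
#' no qualifying peak (agranular cortex) are marked unresolved; they are
#' positioned by the smoothing steps of [refine_layer4()].
#'
#' @param profiles a [profile_set()] in the `"layer12-white"` frame (see
#'   [resample_between_surfaces()]).
#' @param upper the layer I/II [layer_surface()] providing chord upper ends.
#' @param pair the [surface_pair()].
#' @param cfg a [detection_config()].
#' @return A [layer_surface()] in the `"layer12-white"` frame, with
#'   unresolved vertices flagged in `$resolved`.
#' @export
init_layer4 <- function(profiles, upper, pair, cfg = detection_config()) {
  stopifnot(inherits(profiles, "profile_set"),
            identical(profiles$frame, "layer12-white"))
  n <- profiles$n
  nv <- nrow(profiles$samples)
  mask <- profiles$mask & upper$mask
  depth <- rep(NA_real_, nv)
  resolved <- rep(FALSE, nv)
  for (v in which(mask)) {
    s <- profiles$samples[v, ]
    d1 <- c(s[2] - s[1], (s[3:n] - s[1:(n - 2)]) / 2, s[n] - s[n - 1])
    d2 <- c(NA, s[3:n] - 2 * s[2:(n - 1)] + s[1:(n - 2)], NA)
    # the layer II/III inflection follows a descent (the dip after the
    # layer II peak); without this the initial rise into layer II would
    # qualify and its peak would be mistaken for layer IV
    desc <- which(d1 < 0)
    if (!length(desc)) next
    j <- which(d1 > 0 & d2 > 0 & seq_len(n) > desc[1])
    if (!length(j)) next
    pks <- layer4_peak_depths(s, cfg$peak_prominence_frac)
    pks <- pks[pks > (j[1] - 1) / (n - 1)]
    if (length(pks)) { depth[v] <- pks[1]; resolved[v] <- TRUE }
  }
  med <- if (any(resolved)) stats::median(depth[resolved]) else 0.5
  depth[!resolved] <- med
  layer_surface(depth, upper$coords, pair$white$vertices,
                pair$white$triangles, mask = mask, frame = "layer12-white",
                resolved = resolved)
}

# fill unresolved vertices by iterative neighbor averaging of filled values
fill_from_neighbors <- function(x, filled, adj) {
  guard <- 0L
  while (any(!filled) && guard < 1000L) {
    nb_num <- as.numeric(adj %*% ifelse(filled, x, 0))
    nb_den <- as.numeric(adj %*% as.numeric(filled))
    newly <- !filled & nb_den > 0
    if (!any(newly)) break
    x[newly] <- nb_num[newly] / nb_den[newly]
    filled <- filled | newly
    guard <- guard + 1L
  }
  x
}

#' Refine the mid-layer IV surface
#'
#' Iterates three corrections until convergence: (1) *geometric smoothing*
#' of the layer IV mesh without shrinkage ([taubin_smooth()]), projecting
#' the smoothed coordinates back onto the per-vertex chords; (2)
#' *equivolumetric-depth smoothing* — the per-vertex positions are
#' converted to equivolumetric depth between the layer I/II and white
#' surfaces, smoothed across the surface with a Gaussian kernel of
#' `equivol_smooth_fwhm_mm` FWHM, and the surface is rebuilt at the
#' smoothed depths (this repositions unresolved and outlier vertices from
#' their surround); (3) *peak adjustment* — each resolved vertex moves to
#' the nearest qualifying intensity peak of its profile. Unresolved
#' (agranular) vertices participate only through step (2): they receive
#' smoothed depth from their neighbourhood and are never snapped to a peak.
#'
#' Iteration stops when the fraction of vertices that moved by more than
#' one profile sample step falls below `convergence_max_moved_frac`, or at
#' `max_iterations` with a warning; per-iteration moved counts are in
#' attribute `"trace"`.
#'
#' @param surface the initialized layer IV [layer_surface()].
#' @param profiles the [profile_set()] in the `"layer12-white"` frame.
#' @param pair the [surface_pair()].
#' @param upper the layer I/II [layer_surface()].
#' @param cfg a [detection_config()].
#' @return The refined [layer_surface()].
#' @export
refine_layer4 <- function(surface, profiles, pair, upper,
                          cfg = detection_config()) {
  stopifnot(inherits(surface, "layer_surface"),
            identical(surface$frame, "layer12-white"))
  n <- profiles$n
  h <- 1 / (n - 1)
  nv <- length(surface$depth_frac)
  mask <- surface$mask
  resolved <- surface$resolved & mask
  up <- surface$upper_coords
  wh <- surface$lower_coords
  chord <- wh - up
  chord_len2 <- pmax(rowSums(chord^2), 1e-18)
  field <- compute_equivol_field(up, pair)
  adj <- mesh_adjacency(pair$white)
  peaks <- lapply(seq_len(nv), function(v)
    if (resolved[v]) layer4_peak_depths(profiles$samples[v, ],
                                        cfg$peak_prominence_frac)
    else numeric())
  depth <- surface$depth_frac
  trace <- integer()
  for (it in seq_len(cfg$max_iterations)) {
    prev <- depth
    # 1. geometric smoothing of the layer IV mesh, reprojected onto chords
    coords <- up + depth * chord
    sm <- taubin_smooth(surface_mesh(coords, surface$triangles),
                        iterations = cfg$taubin_iters_per_pass)
    depth <- rowSums((sm$vertices - up) * chord) / chord_len2
    depth <- pmin(pmax(depth, 0), 1)
    # 2. smooth equivolumetric depth across the surface, rebuild surface
    f <- chord_to_equivol(field, depth)
    fs <- smooth_scalar_on_surface(f, pair$white, cfg$equivol_smooth_fwhm_mm,
                                   mask = resolved)
    fs <- fill_from_neighbors(fs, resolved | !mask, adj)
    depth <- equivol_to_chord(field, pmin(pmax(fs, 0), 1))
    # 3. local adjustment to the nearest profile peak (resolved only)
    for (v in which(resolved)) {
      if (length(peaks[[v]]))
        depth[v] <- nearest_candidate(peaks[[v]], depth[v])
    }
    moved <- sum(abs(depth - prev) > h & mask)
    trace <- c(trace, moved)
    if (moved / max(1, sum(mask)) < cfg$convergence_max_moved_frac) break
    if (it == cfg$max_iterations)
      warning(sprintf(
        "layer IV refinement not converged after %d iterations (moved counts: %s)",
        it, paste(trace, collapse = " ")))
  }
  out <- layer_surface(depth, up, wh, surface$triangles, mask = mask,
                       frame = "layer12-white", resolved = resolved)
  attr(out, "trace") <- trace
  out
}

#' Detect the layer I/II boundary and mid-layer IV surfaces
#'
#' Runs the full laminar detection pipeline on a (smoothed) intensity
#' volume and a linked white/pial surface pair: profile extraction,
#' layer I/II initialization and refinement, profile re-extraction between
#' the layer I/II and white surfaces, and layer IV initialization and
#' refinement. The pipeline is deterministic: repeated runs on the same
#' inputs give bit-identical outputs.
#'
#' @param vol an [intensity_volume()]; pass `smooth_cfg` to apply
#'   [anisotropic_smooth()] first.
#' @param pair a [surface_pair()].
#' @param cls optional [tissue_classification()] used to initialize the
#'   layer I/II boundary.
#' @param cfg a [detection_config()].
#' @param n profile samples (default 100).
#' @param smooth_cfg optional [smoothing_config()] applied to `vol` before
#'   profile extraction.
#' @return An object of class `laminar_detection`: a list with `layer12`
#'   (a `"pial-white"` [layer_surface()]), `layer4` (a `"layer12-white"`
#'   [layer_surface()] with the pial-frame depth in `$depth_frac_pial`),
#'   and `qc` (moved-vertex traces, masked and unresolved counts).
#' @export
detect_layers <- function(vol, pair, cls = NULL, cfg = detection_config(),
                          n = 100, smooth_cfg = NULL) {
  if (!is.null(smooth_cfg)) vol <- anisotropic_smooth(vol, smooth_cfg)
  profiles <- extract_profiles(vol, pair, n = n)
  l12 <- refine_layer12(init_layer12(profiles, pair, cls, cfg),
                        profiles, pair, cfg)
  psub <- resample_between_surfaces(vol, l12, pair, n = n)
  l4 <- refine_layer4(init_layer4(psub, l12, pair, cfg), psub, pair, l12, cfg)
  l4$depth_frac_pial <- l12$depth_frac + l4$depth_frac * (1 - l12$depth_frac)
  qc <- list(
    layer12_trace = attr(l12, "trace"),
    layer4_trace = attr(l4, "trace"),
    masked = sum(!(l12$mask & l4$mask)),
    unresolved = sum(l4$mask & !l4$resolved))
  structure(list(layer12 = l12, layer4 = l4, qc = qc),
            class = "laminar_detection")
}

#' @export
print.laminar_detection <- function(x, ...) {
  cat("<laminar_detection>\n  layer I/II: ")
  print(x$layer12)
  cat("  layer IV:   ")
  print(x$layer4)
  cat(sprintf("  qc: %d masked, %d unresolved; traces I/II [%s], IV [%s]\n",
              x$qc$masked, x$qc$unresolved,
              paste(x$qc$layer12_trace, collapse = " "),
              paste(x$qc$layer4_trace, collapse = " ")))
  invisible(x)
}
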