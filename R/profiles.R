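#' Cortical intensity profile set
#'
#' Per-vertex staining-intensity profiles sampled along the chord between
#' linked surface vertices. Sample 1 lies on the upper (pial or layer I/II)
#' end and sample `n` on the white end; `depth_frac` is the corresponding
#' equally spaced fractional depth in `[0, 1]` (0 = upper, 1 = white).
#'
#' @param samples numeric matrix, one profile per row (vertices x n).
#' @param depth_frac length-n strictly increasing, equally spaced depths.
#' @param seg_length_mm per-vertex chord length, mm.
#' @param mask logical per-vertex validity (zero-length chords are masked).
#' @param frame which chord the profiles span: `"pial-white"` or
#'   `"layer12-white"`.
#' @return An object of class `profile_set`.
#' @export
profile_set <- function(samples, depth_frac, seg_length_mm, mask = NULL,
                        frame = "pial-white") {
  samples <- as.matrix(samples)
  n <- ncol(samples)
  if (n < 2L) stop("profiles need n >= 2 samples")
  if (length(depth_frac) != n) stop("depth_frac length mismatch")
  if (is.null(mask)) mask <- rep(TRUE, nrow(samples))
  structure(list(samples = samples, depth_frac = as.numeric(depth_frac),
                 seg_length_mm = as.numeric(seg_length_mm),
                 mask = as.logical(mask), n = n, frame = frame),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("<profile_set> %d profiles (%d valid) x %d samples [%s]\n",
              nrow(x$samples), sum(x$mask), x$n, x$frame))
  invisible(x)
}

profile_points <- function(upper, lower, n) {
  # (nv * n) x 3 matrix of sample points, vertex-major
  t <- seq(0, 1, length.out = n)
  nv <- nrow(upper)
  d <- lower - upper
  list(points = cbind(rep(upper[, 1], each = n) + rep(d[, 1], each = n) * t,
                      rep(upper[, 2], each = n) + rep(d[, 2], each = n) * t,
                      rep(upper[, 3], each = n) + rep(d[, 3], each = n) * t),
       t = t, nv = nv)
}

sample_profiles <- function(vol, upper, lower, n, oob, frame) {
  seg <- sqrt(rowSums((lower - upper)^2))
  valid <- seg > 1e-9
  pp <- profile_points(upper, lower, n)
  vals <- sample_trilinear(vol, pp$points, oob = oob)
  m <- matrix(vals, nrow = pp$nv, ncol = n, byrow = TRUE)
  m[!valid, ] <- NA_real_
  profile_set(m, pp$t, seg, mask = valid, frame = frame)
}

#' Extract staining-intensity profiles between linked vertices
#'
#' For each linked vertex pair, samples the volume along the straight chord
#' from the pial vertex to the white vertex at `n` equidistant points by
#' trilinear interpolation. Zero-length chords yield a masked (invalid)
#' profile rather than an error.
#'
#' @param vol an [intensity_volume()] (typically anisotropically smoothed).
#' @param pair a [surface_pair()].
#' @param n number of sample points per profile (default 100).
#' @param oob out-of-bounds policy passed to [sample_trilinear()]; default
#'   `"halfvoxel"` clamps endpoints within half a voxel of the boundary.
#' @return A [profile_set()] in the `"pial-white"` frame.
#' @export
extract_profiles <- function(vol, pair, n = 100, oob = "halfvoxel") {
  stopifnot(inherits(pair, "surface_pair"), n >= 2)
  sample_profiles(vol, pair$pial$vertices, pair$white$vertices, n, oob,
                  "pial-white")
}

#' Re-extract profiles between the layer I/II surface and the white surface
#'
#' As [extract_profiles()], but the upper endpoint of each chord is the
#' detected layer I/II boundary instead of the pial vertex, so that layer IV
#' is located within the cell-dense cortex only.
#'
#' @param vol an [intensity_volume()].
#' @param upper a [layer_surface()] (or any n x 3 coordinate matrix) lying
#'   between pial and white at every vertex.
#' @param pair a [surface_pair()].
#' @param n number of sample points (default 100).
#' @param oob out-of-bounds policy, see [extract_profiles()].
#' @return A [profile_set()] in the `"layer12-white"` frame.
#' @export
resample_between_surfaces <- function(vol, upper, pair, n = 100,
                                      oob = "halfvoxel") {
  stopifnot(inherits(pair, "surface_pair"), n >= 2)
  up <- if (inherits(upper, "layer_surface")) upper$coords else as_points(upper)
  sample_profiles(vol, up, pair$white$vertices, n, oob, "layer12-white")
}

#' First derivative of profiles with respect to fractional depth
#'
#' Central differences in the interior, one-sided at the ends, per unit
#' `depth_frac` (so a profile rising linearly from 0 to `s` has gradient
#' `s` everywhere).
#'
#' @param p a [profile_set()] or a numeric vector/matrix of samples.
#' @param depth_frac sample depths if `p` is not a profile set (defaults to
#'   equally spaced on `[0, 1]`).
#' @return Gradient in the same shape as the input samples.
#' @export
profile_gradient <- function(p, depth_frac = NULL) {
  if (inherits(p, "profile_set")) {
    m <- p$samples
    depth_frac <- p$depth_frac
  } else if (is.null(dim(p))) {
    m <- matrix(p, nrow = 1)
  } else m <- as.matrix(p)
  n <- ncol(m)
  if (n < 3L) stop("need n >= 3 samples")
  if (is.null(depth_frac)) depth_frac <- seq(0, 1, length.out = n)
  h <- depth_frac[2] - depth_frac[1]
  g <- matrix(NA_real_, nrow(m), n)
  g[, 2:(n - 1)] <- (m[, 3:n] - m[, 1:(n - 2)]) / (2 * h)
  g[, 1] <- (m[, 2] - m[, 1]) / h
  g[, n] <- (m[, n] - m[, n - 1]) / h
  if (inherits(p, "profile_set") || !is.null(dim(p))) g else as.numeric(g)
}

# ---- simulated laminar density profiles -----------------------------------

#' Cortical area laminar description
#'
#' Per-layer thickness and neuronal density for one cortical area, in the
#' style of classical quantitative cytoarchitecture tables: layer thickness
#' gives the width and neuronal packing density the height of a
#' histogram-like laminar profile.
#'
#' @param area_code short area code (e.g. `"FD"`, `"OA"`).
#' @param thickness_mm per-layer thickness, mm (layers ordered pial to
#'   white; sublayers allowed). All >= 0 with a positive sum.
#' @param density per-layer neuronal density (cells per unit volume,
#'   arbitrary but consistent units). All >= 0.
#' @param layers optional layer names.
#' @return An object of class `von_economo_area`.
#' @export
von_economo_area <- function(area_code, thickness_mm, density,
                             layers = NULL) {
  if (length(thickness_mm) != length(density))
    stop("thickness and density must have equal length")
  if (any(thickness_mm < 0) || any(density < 0))
    stop("thickness and density must be >= 0")
  if (sum(thickness_mm) <= 0) stop("total thickness must be positive")
  if (is.null(layers)) layers <- as.roman(seq_along(thickness_mm))
  structure(list(area_code = area_code,
                 thickness_mm = as.numeric(thickness_mm),
                 density = as.numeric(density),
                 layers = as.character(layers)),
            class = "von_economo_area")
}

#' Read a laminar thickness/density table
#'
#' Tab- or whitespace-delimited text with columns `area`, `layer`,
#' `thickness_mm`, `density`; one row per layer, layers ordered pial to
#' white within each area. A small synthetic illustrative table ships at
#' `system.file("extdata", "synthetic_area_table.tsv", package = "laminae3d")`.
#'
#' @param path file path.
#' @return named list of [von_economo_area()] objects.
#' @export
read_area_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("area", "layer", "thickness_mm", "density")
  if (!all(need %in% names(tab)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(tab, factor(tab$area, levels = unique(tab$area))),
                function(a) von_economo_area(a$area[1], a$thickness_mm,
                                             a$density, a$layer))
  out
}

#' Simulate a laminar density profile
#'
#' Builds the histogram-like profile of a cortical area — piecewise-constant
#' density against cumulative-thickness fraction — resampled to `n`
#' equidistant points and smoothed with a 1D Gaussian whose FWHM is
#' `smooth_fwhm_frac` of the total thickness, mirroring the smoothing
#' applied to measured intensity profiles. The default fraction 0.054
#' corresponds to a 0.163 mm kernel on a 3 mm cortex.
#'
#' @param area a [von_economo_area()].
#' @param n number of samples (default 100).
#' @param smooth_fwhm_frac smoothing FWHM as a fraction of total thickness.
#' @return list with `samples` (length n) and `depth_frac` (0 = pial,
#'   1 = white).
#' @export
simulate_von_economo_profile <- function(area, n = 100,
                                         smooth_fwhm_frac = 0.054) {
  stopifnot(inherits(area, "von_economo_area"), n >= 2)
  tt <- sum(area$thickness_mm)
  breaks <- cumsum(area$thickness_mm) / tt
  depth <- seq(0, 1, length.out = n)
  band <- findInterval(depth, c(0, breaks), rightmost.closed = TRUE,
                       all.inside = TRUE)
  samples <- area$density[band]
  samples <- smooth_profile_gaussian(samples, smooth_fwhm_frac * (n - 1))
  list(samples = samples, depth_frac = depth)
}
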