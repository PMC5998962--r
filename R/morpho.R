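#' Discrete mean curvature of a mesh
#'
#' Cotangent-Laplacian mean curvature per vertex: `H = |L x| / (2 A)` with
#' the barycentric vertex area `A`, signed by the outward vertex normal so
#' that outward-convex gyral crowns are positive and sulcal fundi negative.
#' Requires consistently oriented (outward) triangles. Boundary vertices
#' are masked.
#'
#' @param mesh a [surface_mesh()].
#' @return A [vertex_scalar_map()] in mm^-1.
#' @export
mean_curvature <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices; tr <- mesh$triangles
  nv <- nrow(v)
  # cotangent weights per triangle corner
  lap <- matrix(0, nv, 3)
  wsum <- numeric(nv)
  corners <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  acc_i <- integer(0); acc_j <- integer(0); acc_w <- numeric(0)
  for (c in corners) {
    a <- tr[, c[1]]; b <- tr[, c[2]]; o <- tr[, c[3]]
    # angle at o faces edge (a, b)
    u <- v[a, , drop = FALSE] - v[o, , drop = FALSE]
    w <- v[b, , drop = FALSE] - v[o, , drop = FALSE]
    cosang <- rowSums(u * w)
    cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
    cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
    cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
    sinang <- sqrt(cx^2 + cy^2 + cz^2)
    cot <- cosang / pmax(sinang, 1e-12)
    acc_i <- c(acc_i, a, b); acc_j <- c(acc_j, b, a)
    acc_w <- c(acc_w, cot, cot)
  }
  W <- Matrix::sparseMatrix(i = acc_i, j = acc_j, x = acc_w / 2,
                            dims = c(nv, nv))
  dg <- as.numeric(W %*% rep(1, nv))
  Lx <- as.matrix(W %*% v) - dg * v
  A <- vertex_areas(mesh)
  Hn <- Lx / pmax(A, 1e-12)   # mean curvature normal, magnitude 2H
  nrm <- vertex_normals(mesh)
  Hmag <- sqrt(rowSums(Hn^2)) / 2
  # Lx points toward the center of curvature; convex-outward => opposite
  # the outward normal, which this convention counts as positive
  sgn <- -sign(rowSums(Hn * nrm))
  # boundary vertices: those on edges belonging to a single triangle
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e[, 1], e[, 2])
  cnt <- table(key)
  bdry_edges <- e[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
  mask <- rep(TRUE, nv)
  mask[unique(as.vector(bdry_edges))] <- FALSE
  vertex_scalar_map(Hmag * sgn, units = "mm^-1", mask = mask)
}

#' Mid-surface between two linked surfaces
#'
#' Per-vertex midpoint of the chord; the standard carrier for curvature in
#' laminar morphometry is the mid-surface equidistant between the white
#' and layer I/II surfaces.
#'
#' @param a,b linked [surface_mesh()]es (or a [surface_pair()] as `a`, in
#'   which case `b` is ignored); also accepts a [layer_surface()] for
#'   either argument.
#' @return A [surface_mesh()].
#' @export
mid_surface <- function(a, b = NULL) {
  if (inherits(a, "surface_pair")) { b <- a$pial; a <- a$white }
  coords <- function(x) if (inherits(x, "layer_surface")) x$coords else x$vertices
  tris <- function(x) if (inherits(x, "layer_surface")) x$triangles else x$triangles
  surface_mesh((coords(a) + coords(b)) / 2, tris(a))
}

#' Relative (percentage) depth of layer IV
#'
#' Position of the layer IV surface expressed as a percentage of the chord
#' from the layer I/II boundary (0%) to the white surface (100%):
#' `100 * |v_IV - v_I/II| / |v_white - v_I/II|` per vertex. Vertices with a
#' zero-length chord are masked.
#'
#' @param layer4 the layer IV [layer_surface()] (any frame; coordinates are
#'   used).
#' @param layer12 the layer I/II [layer_surface()].
#' @param pair the [surface_pair()].
#' @return A [vertex_scalar_map()] in percent.
#' @export
relative_depth <- function(layer4, layer12, pair) {
  up <- layer12$coords
  den <- sqrt(rowSums((pair$white$vertices - up)^2))
  num <- sqrt(rowSums((layer4$coords - up)^2))
  ok <- den > 1e-9 & layer4$mask & layer12$mask
  vertex_scalar_map(ifelse(ok, 100 * num / pmax(den, 1e-9), 0),
                    units = "%", mask = ok)
}

#' Vertex inclusion mask for morphometry
#'
#' Conjunction of: not in a provided exclusion set (e.g. medial wall /
#' hippocampal labels) and cortical thickness at least `min_thickness_mm`
#' (thinner vertices are biologically implausible and usually mark damaged
#' tissue).
#'
#' @param thickness per-vertex thickness (numeric vector or
#'   [vertex_scalar_map()]), mm.
#' @param exclude logical per-vertex exclusion (e.g. medial wall), or NULL.
#' @param min_thickness_mm threshold, default 0.5 mm.
#' @return logical validity mask.
#' @export
mask_vertices <- function(thickness, exclude = NULL,
                          min_thickness_mm = 0.5) {
  th <- if (inherits(thickness, "vertex_scalar_map")) thickness$values
        else as.numeric(thickness)
  ok <- th >= min_thickness_mm
  if (!is.null(exclude)) ok <- ok & !exclude
  ok
}

#' Polynomial regression of layer depth on curvature with BIC comparison
#'
#' Ordinary least squares fits of relative layer IV depth on mean
#' curvature for polynomial orders 1 (linear), 2 (quadratic) and 3 (cubic),
#' compared via the Bayesian information criterion
#' `BIC = n ln(RSS/n) + k ln(n)` with `k = order + 2` (coefficients,
#' intercept and residual variance). Both maps are expected to be smoothed
#' on the surface beforehand (3 mm FWHM by convention) to remove isolated
#' extreme values. The overall F statistic and p-value test each model
#' against the intercept-only model.
#'
#' @param curvature a [vertex_scalar_map()] (mm^-1) or numeric vector.
#' @param depth a [vertex_scalar_map()] (%) or numeric vector.
#' @param mask optional logical inclusion mask (see [mask_vertices()]);
#'   combined with the maps' own masks.
#' @param orders polynomial orders to fit (default 1:3).
#' @return An object of class `curvdepth_fits`: a list of per-order results
#'   (`order`, `coefficients`, `rss`, `n`, `bic`, `fstat`, `df`, `p`), with
#'   the lowest-BIC order in `$selected`. `as.data.frame()` gives the
#'   summary table.
#' @export
fit_curvature_depth <- function(curvature, depth, mask = NULL,
                                orders = 1:3) {
  gv <- function(x) if (inherits(x, "vertex_scalar_map")) x$values else as.numeric(x)
  gm <- function(x) if (inherits(x, "vertex_scalar_map")) x$mask else rep(TRUE, length(gv(x)))
  x <- gv(curvature); y <- gv(depth)
  ok <- gm(curvature) & gm(depth) & is.finite(x) & is.finite(y)
  if (!is.null(mask)) ok <- ok & mask
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) stop("need >= 10 valid vertices")
  if (stats::var(x) == 0) stop("rank-deficient: curvature is constant")
  fits <- lapply(orders, function(ord) {
    fit <- stats::lm(y ~ stats::poly(x, ord, raw = TRUE))
    rss <- sum(stats::residuals(fit)^2)
    k <- ord + 2
    bic <- n * log(rss / n) + k * log(n)
    tss <- sum((y - mean(y))^2)
    df1 <- ord; df2 <- n - ord - 1
    fstat <- ((tss - rss) / df1) / (rss / df2)
    p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
    co <- stats::coef(fit)
    names(co) <- c("(Intercept)", paste0("beta", seq_len(ord)))
    list(order = ord, coefficients = co, rss = rss, n = n, bic = bic,
         fstat = fstat, df = c(df1, df2), p = p)
  })
  names(fits) <- paste0("order", orders)
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  structure(list(fits = fits, selected = orders[which.min(bics)], n = n),
            class = "curvdepth_fits")
}

#' @export
as.data.frame.curvdepth_fits <- function(x, ...) {
  do.call(rbind, lapply(x$fits, function(f)
    data.frame(order = f$order, n = f$n, rss = f$rss, bic = f$bic,
               fstat = f$fstat, p = f$p,
               beta1 = unname(f$coefficients["beta1"]))))
}

#' @export
print.curvdepth_fits <- function(x, ...) {
  cat(sprintf("<curvdepth_fits> n = %d; selected order: %d (lowest BIC)\n",
              x$n, x$selected))
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Angle between cortical profiles and a section plane
#'
#' The angle at which each cortical traversal meets a 2D section:
#' `alpha = arcsin(|N . (v_white - v_pial)| / |v_white - v_pial|)`, in
#' degrees, where `N` is the unit normal of the section plane. The
#' magnitude is taken (range 0--90 degrees): the thickness overestimation
#' is even in the angle's sign. Invariant to swapping the chord endpoints
#' and to chord scaling. Zero-length chords are masked.
#'
#' @param pair a [surface_pair()].
#' @param normal unit 3-vector normal to the section plane (e.g.
#'   `c(0, 1, 0)` for coronal sections cut along +y).
#' @return A [vertex_scalar_map()] in degrees.
#' @export
section_angle <- function(pair, normal) {
  stopifnot(inherits(pair, "surface_pair"))
  if (abs(sqrt(sum(normal^2)) - 1) > 1e-8) stop("|normal| must be 1")
  d <- pair$white$vertices - pair$pial$vertices
  len <- sqrt(rowSums(d^2))
  ok <- len > 1e-12
  s <- abs(d %*% normal)[, 1] / pmax(len, 1e-12)
  vertex_scalar_map(ifelse(ok, asin(pmin(s, 1)) * 180 / pi, 0),
                    units = "deg", mask = ok)
}

#' 2D thickness overestimation from oblique sectioning
#'
#' The multiplicative error made when measuring cortical thickness on a 2D
#' section that the cortical traversal meets at angle `alpha`:
#' `100 * (1 / cos(alpha) - 1)` percent. Strictly increasing and convex on
#' `[0, 90)` degrees, zero at zero; at 18 degrees the overestimation
#' reaches 5%. Angles >= 90 degrees are undefined and returned masked
#' (`NA`) with a warning.
#'
#' @param alpha_deg angle(s) in degrees, numeric or [vertex_scalar_map()].
#' @return Overestimation in percent, same shape as the input.
#' @export
overestimation_error <- function(alpha_deg) {
  if (inherits(alpha_deg, "vertex_scalar_map")) {
    v <- overestimation_error(alpha_deg$values)
    return(vertex_scalar_map(ifelse(is.na(v), 0, v), units = "%",
                             mask = alpha_deg$mask & !is.na(v)))
  }
  if (any(alpha_deg < 0, na.rm = TRUE)) stop("alpha must be >= 0")
  bad <- alpha_deg >= 90
  if (any(bad, na.rm = TRUE))
    warning("angles >= 90 degrees are undefined; returned as NA")
  out <- 100 * (1 / cos(alpha_deg * pi / 180) - 1)
  out[bad] <- NA_real_
  out
}
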