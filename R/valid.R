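#' Manual delineation of one histological sample
#'
#' Named polylines delineating the pial surface, the layer I/II boundary,
#' the upper and lower limits of layer IV, and the gray/white border, drawn
#' on one 2D section and expressed in in-plane world coordinates (mm). The
#' section plane is axis-aligned: `axis` names the world axis normal to the
#' plane and `coord` its position; in-plane coordinates are the remaining
#' two world axes in order.
#'
#' @param sample_id identifier.
#' @param axis section normal axis: `"x"`, `"y"` or `"z"`.
#' @param coord world coordinate (mm) of the plane along `axis`.
#' @param polylines named list of k x 2 matrices; recognised names:
#'   `pial`, `layer12`, `layer4_upper`, `layer4_lower`, `white`. Each
#'   ordered along the cortex.
#' @return An object of class `manual_delineation`.
#' @export
manual_delineation <- function(sample_id, axis, coord, polylines) {
  axis <- match.arg(axis, c("x", "y", "z"))
  stopifnot(is.list(polylines), length(names(polylines)) == length(polylines))
  polylines <- lapply(polylines, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L) stop("polylines must be k x 2")
    storage.mode(p) <- "double"
    p
  })
  structure(list(sample_id = sample_id, axis = axis, coord = coord,
                 polylines = polylines),
            class = "manual_delineation")
}

#' @export
print.manual_delineation <- function(x, ...) {
  cat(sprintf("<manual_delineation> sample %s, plane %s = %g mm; polylines: %s\n",
              x$sample_id, x$axis, x$coord,
              paste(names(x$polylines), collapse = ", ")))
  invisible(x)
}

#' Read and write delineations as JSON
#'
#' @param del a [manual_delineation()].
#' @param path file path.
#' @return `read_delineation()` returns a [manual_delineation()].
#' @export
write_delineation <- function(del, path) {
  stopifnot(inherits(del, "manual_delineation"))
  jsonlite::write_json(
    list(sample_id = del$sample_id, axis = del$axis, coord = del$coord,
         polylines = lapply(del$polylines, unname)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_delineation
#' @export
read_delineation <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  manual_delineation(j$sample_id, j$axis, j$coord,
                     lapply(j$polylines, function(p) matrix(p, ncol = 2)))
}

# in-plane axes for an axis-aligned plane
plane_axes <- function(axis) switch(axis, x = c(2L, 3L), y = c(1L, 3L),
                                    z = c(1L, 2L))

#' Intersect a mesh with an axis-aligned plane
#'
#' Returns the points where mesh edges cross the plane, in in-plane 2D
#' coordinates, with any per-vertex scalar linearly interpolated onto the
#' crossing points.
#'
#' @param mesh a [surface_mesh()] (or [layer_surface()]).
#' @param axis,coord plane definition as in [manual_delineation()].
#' @param values optional per-vertex scalar to interpolate.
#' @param mask optional per-vertex validity; edges with an invalid end are
#'   skipped.
#' @return list with `points` (k x 2 in-plane mm) and `values` (length k or
#'   NULL).
#' @export
mesh_plane_intersection <- function(mesh, axis, coord, values = NULL,
                                    mask = NULL) {
  if (inherits(mesh, "layer_surface")) {
    if (is.null(mask)) mask <- mesh$mask
    mesh <- layer_mesh(mesh)
  }
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  v <- mesh$vertices
  if (is.null(mask)) mask <- rep(TRUE, nrow(v))
  e <- mesh_edges(mesh)
  a <- v[e[, 1], ax] - coord
  b <- v[e[, 2], ax] - coord
  cross <- (a * b < 0) & mask[e[, 1]] & mask[e[, 2]]
  if (!any(cross)) return(list(points = matrix(0, 0, 2), values = NULL))
  e <- e[cross, , drop = FALSE]
  t <- a[cross] / (a[cross] - b[cross])
  p <- v[e[, 1], , drop = FALSE] +
    t * (v[e[, 2], , drop = FALSE] - v[e[, 1], , drop = FALSE])
  ip <- plane_axes(c("x", "y", "z")[ax])
  out <- list(points = p[, ip, drop = FALSE], values = NULL)
  if (!is.null(values))
    out$values <- values[e[, 1]] + t * (values[e[, 2]] - values[e[, 1]])
  out
}

# distance from points (k x 2) to a polyline; returns nearest distance and
# the nearest point on the polyline
polyline_distance <- function(points, poly) {
  k <- nrow(points)
  best <- rep(Inf, k)
  bestp <- matrix(NA_real_, k, 2)
  for (s in seq_len(nrow(poly) - 1)) {
    a <- poly[s, ]; b <- poly[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, k) else
      pmin(pmax(((points[, 1] - a[1]) * ab[1] +
                 (points[, 2] - a[2]) * ab[2]) / len2, 0), 1)
    px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]
    d <- sqrt((points[, 1] - px)^2 + (points[, 2] - py)^2)
    upd <- d < best
    best[upd] <- d[upd]
    bestp[upd, ] <- cbind(px, py)[upd, , drop = FALSE]
  }
  list(distance = best, nearest = bestp)
}

#' Signed distance from an automatic surface to a manual delineation
#'
#' Intersects the automatically detected layer surface with the sample's
#' section plane and measures, for each intersection point, the nearest
#' distance to the corresponding manual polyline. The sign is negative
#' when the automatic surface lies closer to the white matter than the
#' manual line and positive when it lies closer to the pial surface
#' (orientation taken from the delineation's `white` polyline, falling
#' back to `pial` if absent).
#'
#' @param auto a [layer_surface()] (or [surface_mesh()]).
#' @param manual a [manual_delineation()].
#' @param structure name of the manual polyline to compare against
#'   (default `"layer12"`).
#' @return data.frame with in-plane coordinates and `distance_um` (signed,
#'   micrometres); empty (with a warning) if the surface does not
#'   intersect the plane.
#' @export
surface_to_manual_distance <- function(auto, manual,
                                       structure = "layer12") {
  stopifnot(inherits(manual, "manual_delineation"))
  poly <- manual$polylines[[structure]]
  if (is.null(poly)) stop("manual delineation lacks polyline: ", structure)
  ix <- mesh_plane_intersection(auto, manual$axis, manual$coord)
  if (nrow(ix$points) == 0) {
    warning("surface does not intersect the section plane")
    return(data.frame(u = numeric(), v = numeric(), distance_um = numeric()))
  }
  pd <- polyline_distance(ix$points, poly)
  ref <- manual$polylines[["white"]]
  sgn <- rep(1, nrow(ix$points))
  if (!is.null(ref)) {
    d_auto <- polyline_distance(ix$points, ref)$distance
    d_manual <- polyline_distance(pd$nearest, ref)$distance
    sgn <- ifelse(d_auto < d_manual, -1, 1)   # closer to white => negative
  } else if (!is.null(manual$polylines[["pial"]])) {
    ref <- manual$polylines[["pial"]]
    d_auto <- polyline_distance(ix$points, ref)$distance
    d_manual <- polyline_distance(pd$nearest, ref)$distance
    sgn <- ifelse(d_auto > d_manual, -1, 1)
  }
  data.frame(u = ix$points[, 1], v = ix$points[, 2],
             distance_um = sgn * pd$distance * 1000)
}

#' Normality and zero-mean tests of per-sample distance errors
#'
#' Anderson--Darling normality test (with estimated mean and variance,
#' Stephens' case-3 p approximation, via \pkg{nortest}) on the per-sample
#' mean distances, followed by a one-sample t-test of mean zero — i.e.
#' whether a systematically different surface is being identified.
#'
#' @param sample_means numeric vector of per-sample mean distances (um);
#'   at least 3 (the AD test itself needs at least 8 and reports `NA`
#'   below that).
#' @param alternative t-test alternative (default `"two.sided"`).
#' @return list with `ad` (`A`, `p`) and `t` (`t`, `p`, `df`); with zero
#'   variance the statistics are `NA` and a note is set.
#' @export
distance_tests <- function(sample_means, alternative = "two.sided") {
  x <- as.numeric(sample_means)
  if (length(x) < 3) stop("need >= 3 samples")
  if (stats::sd(x) == 0) {
    return(list(ad = list(A = NA_real_, p = NA_real_),
                t = list(t = NA_real_, p = NA_real_, df = length(x) - 1),
                note = "zero variance: t statistic undefined"))
  }
  ad <- if (length(x) >= 8) nortest::ad.test(x) else
    list(statistic = NA_real_, p.value = NA_real_)
  tt <- stats::t.test(x, mu = 0, alternative = alternative)
  list(ad = list(A = unname(ad$statistic), p = ad$p.value),
       t = list(t = unname(tt$statistic), p = tt$p.value,
                df = unname(tt$parameter)))
}

#' Correlation of automatic and manual relative layer IV depth
#'
#' Pairs each automatic layer IV intersection point with the nearest
#' position on the manual mid-layer IV line (midway between the upper and
#' lower layer IV limits), computes the manual relative depth there as the
#' percentage position between the layer I/II and white polylines, and
#' returns the Pearson correlation with the automatic relative depth.
#'
#' @param auto_depth numeric vector of automatic relative depths (%), one
#'   per intersection point.
#' @param auto_points k x 2 in-plane coordinates of the intersection
#'   points.
#' @param manual a [manual_delineation()] with `layer4_upper`,
#'   `layer4_lower`, `layer12` and `white` polylines.
#' @return list with `r` (Pearson; `NA` with a note when either series is
#'   constant), `n`, and the paired `manual_depth` values.
#' @export
relative_depth_correlation <- function(auto_depth, auto_points, manual) {
  stopifnot(inherits(manual, "manual_delineation"))
  need <- c("layer4_upper", "layer4_lower", "layer12", "white")
  if (!all(need %in% names(manual$polylines)))
    stop("manual delineation lacks polylines: ",
         paste(setdiff(need, names(manual$polylines)), collapse = ", "))
  if (length(auto_depth) < 3) stop("need >= 3 paired positions")
  upr <- manual$polylines$layer4_upper
  lwr <- manual$polylines$layer4_lower
  k <- min(nrow(upr), nrow(lwr))
  mid <- (upr[seq_len(k), , drop = FALSE] + lwr[seq_len(k), , drop = FALSE]) / 2
  near <- polyline_distance(as.matrix(auto_points), mid)$nearest
  d12 <- polyline_distance(near, manual$polylines$layer12)$distance
  dwh <- polyline_distance(near, manual$polylines$white)$distance
  manual_depth <- 100 * d12 / (d12 + dwh)
  if (stats::sd(auto_depth) == 0 || stats::sd(manual_depth) == 0)
    return(list(r = NA_real_, n = length(auto_depth),
                manual_depth = manual_depth,
                note = "constant series: correlation undefined"))
  list(r = stats::cor(auto_depth, manual_depth), n = length(auto_depth),
       manual_depth = manual_depth)
}

#' Validation report against a set of manual delineations
#'
#' Convenience wrapper: per-sample signed and unsigned mean distances for a
#' detected surface, pooled distance tests, and (when layer IV limits are
#' delineated) the per-sample relative-depth correlations.
#'
#' @param detection a `laminar_detection` (see [detect_layers()]).
#' @param delineations list of [manual_delineation()]s.
#' @param pair the [surface_pair()].
#' @return list with `per_sample` (data.frame), `tests` (for both layers),
#'   and `mean_r`.
#' @export
validation_report <- function(detection, delineations, pair) {
  l12 <- detection$layer12
  l4 <- detection$layer4
  rd <- relative_depth(l4, l12, pair)
  rows <- lapply(delineations, function(del) {
    d12 <- surface_to_manual_distance(l12, del, "layer12")
    mid4 <- (polyline_distance(del$polylines$layer4_upper,
                               del$polylines$layer4_lower)$nearest +
               del$polylines$layer4_upper) / 2
    del4 <- del
    del4$polylines$layer4_mid <- mid4
    d4 <- surface_to_manual_distance(l4, del4, "layer4_mid")
    ix <- mesh_plane_intersection(l4, del$axis, del$coord, values = rd$values,
                                  mask = l4$mask & rd$mask)
    r <- if (nrow(ix$points) >= 3)
      relative_depth_correlation(ix$values, ix$points, del)$r else NA_real_
    data.frame(sample_id = del$sample_id,
               layer12_signed_um = mean(d12$distance_um),
               layer12_unsigned_um = mean(abs(d12$distance_um)),
               layer4_signed_um = mean(d4$distance_um),
               layer4_unsigned_um = mean(abs(d4$distance_um)),
               r = r)
  })
  per_sample <- do.call(rbind, rows)
  tests <- list()
  if (nrow(per_sample) >= 3) {
    tests$layer12 <- distance_tests(per_sample$layer12_signed_um)
    tests$layer4 <- distance_tests(per_sample$layer4_signed_um)
  }
  list(per_sample = per_sample, tests = tests,
       mean_r = mean(per_sample$r, na.rm = TRUE))
}
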