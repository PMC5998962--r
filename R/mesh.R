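#' Triangle surface mesh
#'
#' @param vertices n x 3 matrix of world coordinates (mm).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles) {
  vertices <- as_points(vertices)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    stop("triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Linked white/pial surface pair
#'
#' White and pial meshes with identical triangulation and one-to-one vertex
#' correspondence by index: vertex `i` of the pial mesh is linked to vertex
#' `i` of the white mesh, and the chord between them is the cortical
#' traversal used for intensity profiles.
#'
#' @param white,pial [surface_mesh()] objects with identical vertex count
#'   and identical triangle topology.
#' @return An object of class `surface_pair`.
#' @export
surface_pair <- function(white, pial) {
  stopifnot(inherits(white, "surface_mesh"), inherits(pial, "surface_mesh"))
  if (nrow(white$vertices) != nrow(pial$vertices))
    stop("white and pial must have identical vertex count")
  if (!identical(white$triangles, pial$triangles))
    stop("white and pial must share triangle topology")
  structure(list(white = white, pial = pial), class = "surface_pair")
}

#' @export
print.surface_pair <- function(x, ...) {
  cat(sprintf("<surface_pair> %d linked vertices, %d triangles\n",
              nrow(x$white$vertices), nrow(x$white$triangles)))
  invisible(x)
}

#' Per-vertex cortical thickness
#'
#' Euclidean chord length `|v_pial - v_white|` per linked vertex, mm.
#'
#' @param pair a [surface_pair()].
#' @return numeric vector, mm.
#' @export
pair_thickness <- function(pair) {
  stopifnot(inherits(pair, "surface_pair"))
  sqrt(rowSums((pair$pial$vertices - pair$white$vertices)^2))
}

#' Per-vertex scalar map
#'
#' A scalar value per mesh vertex with a units tag and an optional validity
#' mask; masked entries are excluded from all statistics and from
#' on-surface smoothing.
#'
#' @param values numeric vector, one value per vertex.
#' @param units units tag (free text, e.g. `"mm^-1"`, `"%"`, `"frac"`).
#' @param mask logical vector, `TRUE` for valid vertices (default all).
#' @return An object of class `vertex_scalar_map`.
#' @export
vertex_scalar_map <- function(values, units = "", mask = NULL) {
  values <- as.numeric(values)
  if (is.null(mask)) mask <- rep(TRUE, length(values))
  if (length(mask) != length(values))
    stop("mask length must equal values length")
  structure(list(values = values, units = units, mask = as.logical(mask)),
            class = "vertex_scalar_map")
}

#' @export
print.vertex_scalar_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<vertex_scalar_map> %d vertices (%d valid)%s; range [%g, %g]\n",
              length(x$values), sum(x$mask),
              if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              min(v), max(v)))
  invisible(x)
}

# ---- mesh utilities -------------------------------------------------------

triangle_areas <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Per-vertex barycentric area
#'
#' One third of the total area of the triangles incident to each vertex;
#' the discrete area element used by the equivolumetric depth model and the
#' curvature estimator.
#'
#' @param mesh a [surface_mesh()].
#' @return numeric vector of areas (mm^2).
#' @export
vertex_areas <- function(mesh) {
  ta <- triangle_areas(mesh)
  n <- nrow(mesh$vertices)
  acc <- numeric(n)
  for (c in 1:3) {
    s <- rowsum(ta, mesh$triangles[, c])
    acc[as.integer(rownames(s))] <- acc[as.integer(rownames(s))] + s[, 1]
  }
  acc / 3
}

#' Area-weighted outward vertex normals
#'
#' Assumes consistently oriented triangles (counter-clockwise seen from
#' outside). Returns unit normals.
#'
#' @param mesh a [surface_mesh()].
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])  # 2*area-weighted
  n <- matrix(0, nrow(v), 3)
  for (c in 1:3) {
    s <- rowsum(fn, tr[, c])
    ii <- as.integer(rownames(s))
    n[ii, ] <- n[ii, ] + s
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Vertex adjacency of a mesh
#'
#' @param mesh a [surface_mesh()].
#' @return list of integer vectors: for each vertex, the indices of its
#'   one-ring neighbours.
#' @export
mesh_neighbors <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  adj <- split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]), levels = seq_len(n)))
  lapply(adj, as.integer)
}

# sparse uniform adjacency matrix (unweighted, no diagonal)
mesh_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = 1, dims = c(n, n))
}

mean_edge_length <- function(mesh) {
  e <- mesh_edges(mesh)
  d <- mesh$vertices[e[, 1], , drop = FALSE] - mesh$vertices[e[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere; a quasi-uniform closed
#' triangulation used for curvature and smoothing verification.
#'
#' @param subdivisions number of 4-to-1 triangle subdivisions (0 = raw
#'   icosahedron).
#' @param radius sphere radius (mm).
#' @param center length-3 center (mm).
#' @return A [surface_mesh()] with outward-oriented triangles.
#' @export
icosphere <- function(subdivisions = 3, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_key <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
    mids <- new.env()
    vl <- nrow(v)
    newv <- list()
    midpoint <- function(a, b) {
      k <- edge_key(a, b)
      if (!is.null(mids[[k]])) return(mids[[k]])
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      vl <<- vl + 1L
      newv[[length(newv) + 1L]] <<- m
      mids[[k]] <- vl
      vl
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                       c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  v <- v * radius
  v <- sweep(v, 2, center, "+")
  surface_mesh(v, f)
}

# ---- surface I/O ----------------------------------------------------------

#' Read and write surface meshes as Wavefront OBJ
#'
#' Minimal OBJ support: `v` and (triangular) `f` records only. Coordinates
#' round-trip within double-precision text formatting (15 significant
#' digits).
#'
#' @param mesh a [surface_mesh()].
#' @param path file path.
#' @return `read_surface_obj()` returns a [surface_mesh()].
#' @export
write_surface_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.15g %.15g %.15g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$triangles[, 1],
                     mesh$triangles[, 2], mesh$triangles[, 3]), con)
  invisible(path)
}

#' @rdname write_surface_obj
#' @export
read_surface_obj <- function(path) {
  ln <- readLines(path)
  vlines <- ln[startsWith(ln, "v ")]
  flines <- ln[startsWith(ln, "f ")]
  v <- matrix(scan(text = sub("^v ", "", vlines), quiet = TRUE),
              ncol = 3, byrow = TRUE)
  f <- matrix(as.integer(scan(text = gsub("/[0-9/]*", "",
                                          sub("^f ", "", flines)),
                              quiet = TRUE)),
              ncol = 3, byrow = TRUE)
  surface_mesh(v, f)
}

#' Read and write per-vertex scalar maps as plain text
#'
#' One value per line, aligned with the vertex order of the associated
#' mesh; `NA` marks masked vertices.
#'
#' @param map a [vertex_scalar_map()].
#' @param path file path.
#' @param units units tag applied on read.
#' @return `read_scalar_map()` returns a [vertex_scalar_map()].
#' @export
write_scalar_map <- function(map, path) {
  stopifnot(inherits(map, "vertex_scalar_map"))
  v <- map$values
  v[!map$mask] <- NA_real_
  writeLines(format(v, digits = 15, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

#' @rdname write_scalar_map
#' @export
read_scalar_map <- function(path, units = "") {
  ln <- readLines(path)
  v <- rep(NA_real_, length(ln))
  ok <- ln != "NA"
  v[ok] <- as.numeric(ln[ok])
  vertex_scalar_map(ifelse(is.na(v), 0, v), units = units, mask = !is.na(v))
}
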