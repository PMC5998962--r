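#' Intensity volume
#'
#' A 3D scalar grid of staining intensity at isotropic resolution. Axis order
#' is fixed as (x, y, z); the voxel `data[i, j, k]` has its *center* at world
#' coordinate `origin_mm + (c(i, j, k) - 1) * voxel_size_um / 1000` (mm).
#' World units are millimetres for coordinates and micrometres for voxel
#' size; conversions are centralised in [world_to_voxel()] / [voxel_to_world()].
#'
#' Intensity follows the histological convention of this package: background
#' is 0 and values increase with staining intensity (see [invert_intensity()]
#' for raw scans where background is bright).
#'
#' @param data numeric 3D array.
#' @param voxel_size_um positive scalar, isotropic voxel edge in micrometres.
#' @param origin_mm numeric length-3, world coordinate (mm) of the first
#'   voxel center.
#' @return An object of class `intensity_volume`.
#' @export
intensity_volume <- function(data, voxel_size_um, origin_mm = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a positive scalar")
  if (length(origin_mm) != 3L || !all(is.finite(origin_mm)))
    stop("`origin_mm` must be a finite 3-vector")
  structure(
    list(data = data, voxel_size_um = as.numeric(voxel_size_um),
         origin_mm = as.numeric(origin_mm)),
    class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<intensity_volume> %d x %d x %d voxels @ %g um\n",
              d[1], d[2], d[3], x$voxel_size_um))
  cat(sprintf("  origin (mm): %g %g %g   range: [%g, %g]\n",
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' Tissue classification volume
#'
#' Integer labels on the same grid as an [intensity_volume()], with a named
#' codebook. The default codebook is the one emitted by the phantom
#' generator: background, cortical layer I, a single class for cortical
#' layers II--VI ("gray"), and white matter.
#'
#' @param labels integer 3D array.
#' @param voxel_size_um,origin_mm grid geometry, as for [intensity_volume()].
#' @param codebook named integer vector mapping class names to label values;
#'   must cover every value present in `labels`.
#' @return An object of class `tissue_classification`.
#' @export
tissue_classification <- function(labels, voxel_size_um, origin_mm = c(0, 0, 0),
                                  codebook = c(background = 0L, layer1 = 1L,
                                               gray = 2L, white = 3L)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  present <- unique(as.vector(labels))
  if (!all(present %in% codebook))
    stop("codebook does not cover labels present: ",
         paste(setdiff(present, codebook), collapse = ", "))
  structure(
    list(labels = labels, voxel_size_um = as.numeric(voxel_size_um),
         origin_mm = as.numeric(origin_mm), codebook = codebook),
    class = "tissue_classification")
}

#' Convert between world (mm) and continuous voxel coordinates
#'
#' Voxel coordinates are 1-based and continuous: the center of voxel
#' `[i, j, k]` is at voxel coordinate `(i, j, k)`.
#'
#' @param vol an [intensity_volume()] or [tissue_classification()].
#' @param points_mm numeric matrix (n x 3) of world coordinates in mm (a
#'   single point may be given as a length-3 vector).
#' @return n x 3 matrix of continuous voxel coordinates.
#' @export
world_to_voxel <- function(vol, points_mm) {
  p <- as_points(points_mm)
  vs_mm <- vol$voxel_size_um / 1000
  sweep(p, 2, vol$origin_mm) / vs_mm + 1
}

#' @rdname world_to_voxel
#' @param points_vox n x 3 matrix of continuous voxel coordinates.
#' @export
voxel_to_world <- function(vol, points_vox) {
  p <- as_points(points_vox)
  vs_mm <- vol$voxel_size_um / 1000
  sweep((p - 1) * vs_mm, 2, vol$origin_mm, "+")
}

as_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  if (ncol(p) != 3L) stop("points must be n x 3")
  storage.mode(p) <- "double"
  p
}

#' Invert staining intensity
#'
#' Raw scans of cell-body-stained sections have bright background and dark,
#' heavily stained cell bodies. All computations in this package assume the
#' opposite convention (background 0, intensity increasing with staining),
#' so raw volumes are inverted as `max(vol) - vol`.
#'
#' @param vol an [intensity_volume()].
#' @return The inverted [intensity_volume()]. An all-constant volume maps to
#'   all zeros (a message is emitted).
#' @export
invert_intensity <- function(vol) {
  stopifnot(inherits(vol, "intensity_volume"))
  if (!all(is.finite(vol$data))) stop("volume contains non-finite values")
  mx <- max(vol$data)
  if (mx == min(vol$data))
    message("invert_intensity: constant volume, result is all zeros")
  vol$data <- mx - vol$data
  vol
}

#' Subsample a volume by block averaging
#'
#' Downsamples by an integer factor using the mean over non-overlapping
#' `factor^3` blocks, multiplying the voxel size accordingly. A 20 um volume
#' subsampled by factor 2 becomes a 40 um volume with an 8-fold reduction in
#' voxel count.
#'
#' @param vol an [intensity_volume()].
#' @param factor positive integer downsampling factor.
#' @param partial `"truncate"` (default) drops trailing voxels that do not
#'   fill a complete block; `"mean"` averages partial trailing blocks.
#' @return The subsampled [intensity_volume()].
#' @export
subsample_volume <- function(vol, factor, partial = c("truncate", "mean")) {
  stopifnot(inherits(vol, "intensity_volume"))
  partial <- match.arg(partial)
  if (length(factor) != 1L || !is.finite(factor) || factor < 1 ||
      factor != round(factor))
    stop("invalid parameter: `factor` must be a positive integer")
  f <- as.integer(factor)
  if (f == 1L) return(vol)
  d <- dim(vol$data)
  if (any(d < f)) stop("each dimension must be >= factor")
  x <- vol$data
  if (partial == "truncate") {
    nd <- d %/% f
    x <- x[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f), drop = FALSE]
  } else {
    nd <- ceiling(d / f)
    pad <- array(NA_real_, nd * f)
    pad[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- x
    x <- pad
  }
  dim(x) <- c(f, nd[1], f, nd[2], f, nd[3])
  x <- aperm(x, c(1, 3, 5, 2, 4, 6))
  dim(x) <- c(f^3, prod(nd))
  out <- .colMeans(x, f^3, prod(nd), na.rm = TRUE)
  dim(out) <- nd
  # new first-voxel center sits at the mean of the merged voxel centers
  vs_mm <- vol$voxel_size_um / 1000
  intensity_volume(out, vol$voxel_size_um * f,
                   vol$origin_mm + (f - 1) / 2 * vs_mm)
}

#' Decompose a volume into overlapping blocks
#'
#' Splits a volume into `prod(subdivisions)` blocks so that large volumes can
#' be processed piecewise. Blocks are built from a partition of the grid into
#' non-overlapping *cores*, each extended on both sides so that adjacent
#' blocks overlap by at least `min_overlap_um`. With an overlap at least the
#' height of the cortex, any straight cortical profile is contained entirely
#' within at least one block, so profiles sampled near block edges are not
#' affected by smoothing boundary effects.
#'
#' @param vol an [intensity_volume()].
#' @param subdivisions integer, number of subdivisions per axis (scalar or
#'   length 3).
#' @param min_overlap_um minimum overlap between adjacent blocks, micrometres.
#' @return An object of class `block_set`: a list with `blocks` (each a list
#'   with `volume`, `offset` -- 0-based voxel offset -- and `core`, the
#'   1-based index range of the non-overlapping core), plus bookkeeping.
#' @seealso [stitch_blocks()]
#' @export
decompose_blocks <- function(vol, subdivisions, min_overlap_um = 0) {
  stopifnot(inherits(vol, "intensity_volume"))
  if (min_overlap_um < 0) stop("min_overlap_um must be >= 0")
  sub <- as.integer(subdivisions)
  if (length(sub) == 1L) sub <- rep(sub, 3L)
  if (length(sub) != 3L || any(sub < 1L)) stop("subdivisions must be >= 1")
  d <- dim(vol$data)
  ext <- ceiling(ceiling(min_overlap_um / vol$voxel_size_um) / 2)
  ranges <- vector("list", 3L)
  for (ax in 1:3) {
    bounds <- round(seq(0, d[ax], length.out = sub[ax] + 1L))
    core_len <- diff(bounds)
    if (sub[ax] > 1L && any(core_len < 2 * ext))
      stop(sprintf("volume too small to honor the overlap on axis %s",
                   c("x", "y", "z")[ax]))
    ranges[[ax]] <- lapply(seq_len(sub[ax]), function(i) {
      core <- c(bounds[i] + 1L, bounds[i + 1L])
      full <- c(max(1L, core[1] - ext), min(d[ax], core[2] + ext))
      list(core = core, full = full)
    })
  }
  vs_mm <- vol$voxel_size_um / 1000
  blocks <- list()
  for (k in seq_len(sub[3])) for (j in seq_len(sub[2])) for (i in seq_len(sub[1])) {
    rx <- ranges[[1]][[i]]; ry <- ranges[[2]][[j]]; rz <- ranges[[3]][[k]]
    sub_data <- vol$data[rx$full[1]:rx$full[2], ry$full[1]:ry$full[2],
                         rz$full[1]:rz$full[2], drop = FALSE]
    off <- c(rx$full[1], ry$full[1], rz$full[1]) - 1L
    blocks[[length(blocks) + 1L]] <- list(
      volume = intensity_volume(sub_data, vol$voxel_size_um,
                                vol$origin_mm + off * vs_mm),
      offset = off,
      core = rbind(c(rx$core[1], ry$core[1], rz$core[1]),
                   c(rx$core[2], ry$core[2], rz$core[2])))
  }
  structure(list(blocks = blocks, subdivisions = sub,
                 overlap_um = 2 * ext * vol$voxel_size_um,
                 dim = d, voxel_size_um = vol$voxel_size_um,
                 origin_mm = vol$origin_mm),
            class = "block_set")
}

#' @export
print.block_set <- function(x, ...) {
  cat(sprintf("<block_set> %d blocks (%d x %d x %d), overlap %g um\n",
              length(x$blocks), x$subdivisions[1], x$subdivisions[2],
              x$subdivisions[3], x$overlap_um))
  invisible(x)
}

#' Reassemble a block decomposition
#'
#' Stitches the non-overlapping cores of a [decompose_blocks()] result back
#' into a single volume; this reproduces the source volume exactly.
#'
#' @param bs a `block_set`.
#' @return An [intensity_volume()].
#' @export
stitch_blocks <- function(bs) {
  stopifnot(inherits(bs, "block_set"))
  out <- array(NA_real_, bs$dim)
  for (b in bs$blocks) {
    lo <- b$core[1, ] - b$offset
    hi <- b$core[2, ] - b$offset
    out[b$core[1, 1]:b$core[2, 1], b$core[1, 2]:b$core[2, 2],
        b$core[1, 3]:b$core[2, 3]] <-
      b$volume$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  }
  intensity_volume(out, bs$voxel_size_um, bs$origin_mm)
}

#' Trilinear interpolation of a volume
#'
#' Samples the volume at arbitrary world coordinates by trilinear
#' interpolation of the 8 surrounding voxel centers; exact at voxel centers.
#'
#' @param vol an [intensity_volume()].
#' @param points_mm n x 3 matrix (or length-3 vector) of world points, mm.
#' @param oob out-of-bounds policy: `"error"` (default) fails on any point
#'   outside the voxel-center bounding box; `"clamp"` clamps to the nearest
#'   edge; `"halfvoxel"` clamps only points within half a voxel of the
#'   boundary and errors otherwise (the profile-endpoint policy).
#' @return numeric vector of interpolated values.
#' @export
sample_trilinear <- function(vol, points_mm,
                             oob = c("error", "clamp", "halfvoxel")) {
  stopifnot(inherits(vol, "intensity_volume"))
  oob <- match.arg(oob)
  p <- world_to_voxel(vol, points_mm)
  d <- dim(vol$data)
  if (oob == "error") {
    if (any(p < 1 - 1e-9) || any(sweep(p, 2, d) > 1e-9))
      stop("point outside volume bounds")
  } else if (oob == "halfvoxel") {
    if (any(p < 0.5 - 1e-9) || any(sweep(p, 2, d + 0.5) > 1e-9))
      stop("point more than half a voxel outside volume bounds")
  }
  for (ax in 1:3) p[, ax] <- pmin(pmax(p[, ax], 1), d[ax])
  i0 <- floor(p)
  for (ax in 1:3) i0[, ax] <- pmin(i0[, ax], d[ax] - 1)
  i0[, 1] <- pmax(i0[, 1], 1); i0[, 2] <- pmax(i0[, 2], 1)
  i0[, 3] <- pmax(i0[, 3], 1)
  fr <- p - i0
  v <- vol$data
  idx <- function(dx, dy, dz)
    v[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  c00 <- idx(0, 0, 0) * (1 - fx) + idx(1, 0, 0) * fx
  c10 <- idx(0, 1, 0) * (1 - fx) + idx(1, 1, 0) * fx
  c01 <- idx(0, 0, 1) * (1 - fx) + idx(1, 0, 1) * fx
  c11 <- idx(0, 1, 1) * (1 - fx) + idx(1, 1, 1) * fx
  (c00 * (1 - fy) + c10 * fy) * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz
}

#' Nearest-neighbour label lookup
#'
#' @param cls a [tissue_classification()].
#' @param points_mm n x 3 world points (mm); points outside the grid return
#'   `NA`.
#' @return integer vector of labels.
#' @export
sample_labels <- function(cls, points_mm) {
  stopifnot(inherits(cls, "tissue_classification"))
  p <- round(world_to_voxel(cls, points_mm))
  d <- dim(cls$labels)
  ok <- p[, 1] >= 1 & p[, 1] <= d[1] & p[, 2] >= 1 & p[, 2] <= d[2] &
    p[, 3] >= 1 & p[, 3] <= d[3]
  out <- rep(NA_integer_, nrow(p))
  out[ok] <- cls$labels[p[ok, , drop = FALSE]]
  out
}

#' Read and write volumes as NIfTI-1
#'
#' Thin wrappers around \pkg{RNifti}. Voxel size is stored in the NIfTI
#' `pixdim` (mm) and the origin in the sform translation.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param vol an [intensity_volume()].
#' @return `read_volume()` returns an [intensity_volume()];
#'   `write_volume()` returns `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vs_mm <- RNifti::pixdim(img)[1]
  xf <- RNifti::xform(img)
  intensity_volume(array(as.vector(img), dim = dim(img)),
                   voxel_size_um = vs_mm * 1000,
                   origin_mm = xf[1:3, 4])
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "intensity_volume"))
  vs_mm <- vol$voxel_size_um / 1000
  aff <- diag(c(rep(vs_mm, 3), 1))
  aff[1:3, 4] <- vol$origin_mm
  img <- RNifti::asNifti(vol$data, reference = NULL)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::pixdim(img) <- rep(vs_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and write tissue classifications
#'
#' Labels are stored as an integer NIfTI volume plus a JSON codebook
#' side-car (`<path>.codebook.json`).
#'
#' @param cls a [tissue_classification()].
#' @param path path of the NIfTI file.
#' @return `read_labels()` returns a [tissue_classification()].
#' @export
write_labels <- function(cls, path) {
  stopifnot(inherits(cls, "tissue_classification"))
  vol <- intensity_volume(cls$labels + 0, cls$voxel_size_um, cls$origin_mm)
  write_volume(vol, path)
  jsonlite::write_json(as.list(cls$codebook), paste0(path, ".codebook.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  vol <- read_volume(path)
  cb <- unlist(jsonlite::read_json(paste0(path, ".codebook.json")))
  storage.mode(cb) <- "integer"
  lab <- vol$data
  storage.mode(lab) <- "integer"
  tissue_classification(lab, vol$voxel_size_um, vol$origin_mm, codebook = cb)
}
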