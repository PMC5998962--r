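#' Anisotropic smoothing configuration
#'
#' Parameters of the layer-preserving nonlinear diffusion used to denoise
#' histological volumes before profile extraction. The overall extent of
#' smoothing is controlled by `iterations`; the maximum resultant FWHM of
#' the equivalent smoothing kernel is reported by [estimate_max_fwhm()].
#'
#' `edge_sensitivity` is the gradient scale (intensity units per voxel) of
#' the nonlinear diffusivity `g(|grad I|) = 1 / (1 + (|grad I| / kappa)^2)`
#' applied *across* iso-intensity contours: gradients well below it are
#' treated as noise and smoothed; gradients well above it (laminar
#' boundaries) are preserved. Diffusion tangential to the contours always
#' runs at full strength. In the limit of an infinite gradient scale the
#' operator reduces to linear (isotropic Gaussian) diffusion.
#'
#' The defaults (9 iterations, `time_step` 1/6) give a maximum FWHM of
#' 0.163 mm on a 40 um volume.
#'
#' @param iterations non-negative integer number of explicit diffusion steps.
#' @param time_step positive scalar, explicit Euler step in voxel^2 units;
#'   must be <= 1/6 for 3D stability.
#' @param edge_sensitivity positive gradient scale (intensity per voxel).
#' @return An object of class `smoothing_config`.
#' @export
smoothing_config <- function(iterations = 9, time_step = 1/6,
                             edge_sensitivity = 15) {
  if (length(iterations) != 1L || iterations < 0 ||
      iterations != round(iterations))
    stop("iterations must be a non-negative integer")
  if (time_step <= 0 || time_step > 1/6 + 1e-12)
    stop("time_step must be in (0, 1/6]")
  if (edge_sensitivity <= 0) stop("edge_sensitivity must be positive")
  structure(list(iterations = as.integer(iterations),
                 time_step = time_step,
                 edge_sensitivity = edge_sensitivity),
            class = "smoothing_config")
}

#' @export
print.smoothing_config <- function(x, ...) {
  cat(sprintf(
    "<smoothing_config> %d iterations, dt = %.4g, edge sensitivity = %g\n",
    x$iterations, x$time_step, x$edge_sensitivity))
  cat(sprintf("  max FWHM at 40 um voxels: %.3f mm\n",
              estimate_max_fwhm(x, 40)))
  invisible(x)
}

#' Maximum FWHM of the smoothing kernel
#'
#' Closed form for the linear-diffusion limit (infinite edge sensitivity),
#' in which each explicit step adds kernel variance `2 * time_step` voxel^2,
#' so after `iterations` steps
#' `FWHM = voxel_size * sqrt(8 * ln 2 * 2 * iterations * time_step)`.
#' For the nonlinear operator this is the *maximum* resultant FWHM — the
#' smoothing attained tangentially to laminar contours; diffusion across
#' strong gradients is slower.
#'
#' @param cfg a [smoothing_config()].
#' @param voxel_size_um voxel size of the target volume, micrometres.
#' @return FWHM in mm.
#' @export
estimate_max_fwhm <- function(cfg, voxel_size_um = 40) {
  stopifnot(inherits(cfg, "smoothing_config"))
  voxel_size_um / 1000 *
    sqrt(8 * log(2) * 2 * cfg$iterations * cfg$time_step)
}

array_shift <- function(x, ax, by) {
  # shift with replicated (Neumann) boundary; by in {-1, +1}
  d <- dim(x)
  idx <- pmin(pmax(seq_len(d[ax]) + by, 1L), d[ax])
  switch(ax,
         x[idx, , , drop = FALSE],
         x[, idx, , drop = FALSE],
         x[, , idx, drop = FALSE])
}

#' Layer-preserving anisotropic volume smoothing
#'
#' Iterative nonlinear diffusion that smooths maximally in the direction
#' tangential to iso-intensity contours (i.e. along cortical layers) and
#' minimally across them, removing small-scale intensity variation caused
#' by histological artifacts while retaining interlaminar contrast.
#'
#' Each explicit step decomposes the Laplacian into its component along the
#' local gradient direction (`I_nn`, across layers) and the tangential
#' remainder, and advances
#' `I <- I + dt * (lap(I) - I_nn + g(|grad I|) * I_nn)` with
#' `g(s) = 1 / (1 + (s / kappa)^2)`. Where the gradient vanishes the split
#' is isotropic. A discrete maximum principle is enforced: the output range
#' never exceeds the input range. `iterations = 0` returns the input
#' unchanged.
#'
#' @param vol an [intensity_volume()] with finite values.
#' @param cfg a [smoothing_config()].
#' @return The smoothed [intensity_volume()].
#' @export
anisotropic_smooth <- function(vol, cfg = smoothing_config()) {
  stopifnot(inherits(vol, "intensity_volume"),
            inherits(cfg, "smoothing_config"))
  if (!all(is.finite(vol$data))) stop("volume contains non-finite voxels")
  if (cfg$iterations == 0L) return(vol)
  I <- vol$data
  lo <- min(I); hi <- max(I)
  k2 <- cfg$edge_sensitivity^2
  dt <- cfg$time_step
  eps <- 1e-12 * max(1, (hi - lo)^2)
  for (it in seq_len(cfg$iterations)) {
    xp <- array_shift(I, 1L, 1L); xm <- array_shift(I, 1L, -1L)
    yp <- array_shift(I, 2L, 1L); ym <- array_shift(I, 2L, -1L)
    zp <- array_shift(I, 3L, 1L); zm <- array_shift(I, 3L, -1L)
    Ix <- (xp - xm) / 2; Iy <- (yp - ym) / 2; Iz <- (zp - zm) / 2
    Ixx <- xp - 2 * I + xm
    Iyy <- yp - 2 * I + ym
    Izz <- zp - 2 * I + zm
    Ixy <- (array_shift(yp, 1L, 1L) - array_shift(ym, 1L, 1L) -
            array_shift(yp, 1L, -1L) + array_shift(ym, 1L, -1L)) / 4
    Ixz <- (array_shift(zp, 1L, 1L) - array_shift(zm, 1L, 1L) -
            array_shift(zp, 1L, -1L) + array_shift(zm, 1L, -1L)) / 4
    Iyz <- (array_shift(zp, 2L, 1L) - array_shift(zm, 2L, 1L) -
            array_shift(zp, 2L, -1L) + array_shift(zm, 2L, -1L)) / 4
    g2 <- Ix^2 + Iy^2 + Iz^2
    lap <- Ixx + Iyy + Izz
    Inn <- (Ix^2 * Ixx + Iy^2 * Iyy + Iz^2 * Izz +
            2 * (Ix * Iy * Ixy + Ix * Iz * Ixz + Iy * Iz * Iyz))
    flat <- g2 <= eps
    Inn <- ifelse(flat, lap / 3, Inn / pmax(g2, eps))
    g <- 1 / (1 + g2 / k2)
    I <- I + dt * (lap - Inn + g * Inn)
    I[I < lo] <- lo
    I[I > hi] <- hi
  }
  vol$data <- I
  vol
}

# interior local maxima with their prominences; a flat plateau higher than
# both neighbouring runs counts as a single peak at its center sample
profile_peaks <- function(samples) {
  n <- length(samples)
  if (n < 3L) return(list(idx = integer(), prominence = numeric()))
  s <- as.numeric(samples)
  r <- rle(s)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- integer()
  if (k >= 3L) {
    runs <- which(r$values[2:(k - 1)] > r$values[1:(k - 2)] &
                  r$values[2:(k - 1)] > r$values[3:k]) + 1L
    idx <- as.integer(floor((starts[runs] + ends[runs]) / 2))
  }
  if (!length(idx)) return(list(idx = integer(), prominence = numeric()))
  prom <- vapply(idx, function(i) {
    h <- s[i]
    # walk left until a strictly higher point (or the end); key saddle is the
    # minimum along the walk; same on the right
    left <- s[seq_len(i - 1)]
    hl <- which(left > h)
    lmin <- min(left[if (length(hl)) (max(hl) + 1):(i - 1) else seq_len(i - 1)])
    right <- s[(i + 1):n]
    hr <- which(right > h)
    rmin <- min(right[if (length(hr)) seq_len(min(hr) - 1) else seq_along(right)])
    h - max(lmin, rmin)
  }, numeric(1))
  list(idx = idx, prominence = prom)
}

#' Count peaks in an intensity profile
#'
#' Number of strict interior local maxima whose topographic prominence is
#' at least `prominence_frac` times the profile range. Used to select the
#' smoothing level: a well-smoothed six-layer cortical profile retains
#' between 3 and 5 peaks (layers II, IV, VI and occasional sublayers),
#' while under-smoothed profiles carry dozens of noise peaks.
#'
#' @param profile numeric vector of profile samples (length >= 3), or a
#'   single-profile row of a profile set.
#' @param prominence_frac prominence threshold as a fraction of the profile
#'   range, in `[0, 1]`; default 0.05.
#' @return integer peak count (0 for constant or monotone profiles).
#' @export
count_profile_peaks <- function(profile, prominence_frac = 0.05) {
  if (length(profile) < 3L) stop("profile length must be >= 3")
  if (prominence_frac < 0 || prominence_frac > 1)
    stop("prominence_frac must be in [0, 1]")
  rng <- diff(range(profile))
  if (rng == 0) return(0L)
  pk <- profile_peaks(profile)
  sum(pk$prominence >= prominence_frac * rng)
}

#' Smooth a 1D profile with a Gaussian kernel
#'
#' Discrete Gaussian convolution with reflection padding; `fwhm_samples = 0`
#' is the identity.
#'
#' @param samples numeric vector.
#' @param fwhm_samples kernel FWHM in units of sample spacing.
#' @return smoothed numeric vector of the same length.
#' @export
smooth_profile_gaussian <- function(samples, fwhm_samples) {
  if (fwhm_samples <= 0) return(samples)
  sigma <- fwhm_samples / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- length(samples)
  pad <- c(samples[pmin(r:1, n)], samples, samples[pmax(n - (1:r) + 1, 1)])
  as.numeric(stats::filter(pad, k, sides = 2))[(r + 1):(r + n)]
}

#' Gaussian profile sampler at a given smoothing configuration
#'
#' Builds a sampler closure for [select_smoothing_level()] from a fixed set
#' of 1D profiles: at each candidate configuration the profiles are smoothed
#' with a 1D Gaussian whose FWHM equals the configuration's maximum
#' volumetric FWHM ([estimate_max_fwhm()]), converted from mm to profile
#' samples via the sample spacing.
#'
#' @param profiles numeric matrix, one profile per row (or a single vector).
#' @param voxel_size_um voxel size of the notional source volume, um.
#' @param spacing_um distance between consecutive profile samples, um.
#' @return function(cfg) returning the smoothed profile matrix.
#' @export
profile_gaussian_sampler <- function(profiles, voxel_size_um = 40,
                                     spacing_um) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
  force(voxel_size_um); force(spacing_um)
  function(cfg) {
    fwhm_samples <- estimate_max_fwhm(cfg, voxel_size_um) * 1000 / spacing_um
    t(apply(profiles, 1, smooth_profile_gaussian, fwhm_samples = fwhm_samples))
  }
}

#' Select the smoothing level by profile peak counts
#'
#' Increases the number of smoothing iterations from zero until the median
#' peak count over a set of sampled profiles falls within `target_range`
#' (default `[3, 5]`, the count expected from six-layered isocortex), and
#' returns the smallest such configuration.
#'
#' @param sampler function taking a [smoothing_config()] and returning a
#'   matrix of profiles (one per row); typically built with
#'   [profile_gaussian_sampler()] or by smoothing a volume and re-extracting
#'   profiles. Should draw at least 10 profiles from distributed locations.
#' @param target_range numeric length-2, inclusive `[lo, hi]` target for the
#'   median peak count.
#' @param prominence_frac peak prominence threshold, see
#'   [count_profile_peaks()].
#' @param max_iterations search budget (maximum iteration count tried).
#' @param time_step,edge_sensitivity passed to [smoothing_config()].
#' @return The selected [smoothing_config()], with the achieved median peak
#'   count in attribute `"median_peaks"` and the per-level trace in
#'   attribute `"trace"`. Errors if no level within the budget achieves the
#'   target, reporting the achieved counts.
#' @export
select_smoothing_level <- function(sampler, target_range = c(3, 5),
                                   prominence_frac = 0.05,
                                   max_iterations = 60, time_step = 1/6,
                                   edge_sensitivity = 15) {
  stopifnot(length(target_range) == 2L, target_range[1] <= target_range[2])
  trace <- data.frame(iterations = integer(), median_peaks = numeric())
  for (it in 0:max_iterations) {
    cfg <- smoothing_config(it, time_step, edge_sensitivity)
    profs <- sampler(cfg)
    if (is.null(dim(profs))) profs <- matrix(profs, nrow = 1)
    med <- stats::median(apply(profs, 1, count_profile_peaks,
                               prominence_frac = prominence_frac))
    trace <- rbind(trace, data.frame(iterations = it, median_peaks = med))
    if (med >= target_range[1] && med <= target_range[2]) {
      message(sprintf(
        "select_smoothing_level: %d iterations (max FWHM %.3f mm at 40 um), median %g peaks",
        it, estimate_max_fwhm(cfg, 40), med))
      attr(cfg, "median_peaks") <- med
      attr(cfg, "trace") <- trace
      return(cfg)
    }
    if (med < target_range[1]) break  # monotone: more smoothing only lowers it
  }
  stop("no smoothing level within budget reached the target peak range; ",
       "achieved median counts: ",
       paste(sprintf("%d:%g", trace$iterations, trace$median_peaks),
             collapse = " "))
}
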