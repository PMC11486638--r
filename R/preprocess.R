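#' Gaussian smoothing with FWHM given in millimetres
#'
#' Separable Gaussian smoothing, the standard VBM pre-statistics operator.
#' The kernel standard deviation in voxels is
#' `sigma = (fwhm_mm / voxel_size_mm) / (2 * sqrt(2 * log(2)))`; the discrete
#' kernel is sampled at integer offsets out to 4 sigma and normalized to unit
#' sum, and boundaries are zero-padded (gray-matter maps are
#' zero-backgrounded, so boundary leakage is negligible).
#'
#' @param volume a [volume_grid()].
#' @param fwhm_mm positive full width at half maximum, mm.
#' @return Smoothed [volume_grid()].
#' @export
smooth_gaussian <- function(volume, fwhm_mm) {
  stopifnot(is_volume_grid(volume))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm <= 0)
    stop("`fwhm_mm` must be a positive scalar")
  sigma <- fwhm_sigma_voxels(fwhm_mm, volume$voxel_size_mm)
  volume$data <- smooth_array_gaussian(volume$data, sigma)
  volume
}

#' @rdname smooth_gaussian
#' @param voxel_size_mm voxel edge length, mm.
#' @export
fwhm_sigma_voxels <- function(fwhm_mm, voxel_size_mm) {
  (fwhm_mm / voxel_size_mm) / (2 * sqrt(2 * log(2)))
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# separable smoothing of a plain 3D array; sigma in voxels, zero padding
smooth_array_gaussian <- function(a, sigma) {
  if (sigma <= 0) return(a)
  k <- gaussian_kernel_1d(sigma)
  d <- dim(a)
  for (ax in 1:3) {
    n <- d[ax]
    K <- band_matrix(k, n)
    m <- apply_along_first(a, ax, d)
    m <- K %*% m
    a <- restore_from_first(m, ax, d)
  }
  a
}

band_matrix <- function(k, n) {
  r <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (off in -r:r) {
    idx <- seq_len(n)
    src <- idx + off
    ok <- src >= 1L & src <= n
    K[cbind(idx[ok], src[ok])] <- k[off + r + 1L]
  }
  K
}

apply_along_first <- function(a, ax, d) {
  if (ax == 1L) return(matrix(a, d[1], d[2] * d[3]))
  perm <- switch(ax, NULL, c(2L, 1L, 3L), c(3L, 1L, 2L))
  b <- aperm(a, perm)
  matrix(b, d[ax], prod(d[-ax]))
}

restore_from_first <- function(m, ax, d) {
  if (ax == 1L) return(array(m, d))
  if (ax == 2L) return(aperm(array(m, c(d[2], d[1], d[3])), c(2L, 1L, 3L)))
  aperm(array(m, c(d[3], d[1], d[2])), c(2L, 3L, 1L))
}

#' Crop a volume to a fixed shape centred on its foreground
#'
#' Background cropping before feeding volumes to the network. The crop window
#' has exactly `target_shape` voxels and is centred on the centre of the
#' foreground (values > 0) bounding box, clamped to the grid. An all-zero
#' volume is cropped about the grid centre. The returned plan supports exact
#' zero-padded uncropping.
#'
#' @param volume a [volume_grid()].
#' @param target_shape integer vector of 3 target extents, each no larger
#'   than the source extent.
#' @return A list with elements `volume` (the cropped [volume_grid()]) and
#'   `plan` (a `crop_plan` with 1-based `start_index`, `target_shape`,
#'   `source_shape`).
#' @export
crop_to_foreground <- function(volume, target_shape) {
  stopifnot(is_volume_grid(volume))
  target_shape <- as.integer(target_shape)
  d <- dim(volume$data)
  if (length(target_shape) != 3L || any(target_shape < 1L))
    stop("`target_shape` must be 3 positive integers")
  if (any(target_shape > d))
    stop("`target_shape` exceeds the source shape (",
         paste(d, collapse = "x"), ")")
  fg <- which(volume$data > 0, arr.ind = TRUE)
  if (nrow(fg) == 0L) {
    lo <- rep(1L, 3L); hi <- d
  } else {
    lo <- apply(fg, 2L, min); hi <- apply(fg, 2L, max)
    if (any(hi - lo + 1L > target_shape))
      warning("foreground bounding box (",
              paste(hi - lo + 1L, collapse = "x"),
              ") exceeds the crop target; foreground will be truncated")
  }
  centre <- floor((lo + hi) / 2)
  start <- centre - floor(target_shape / 2) + 1L
  start <- pmin(pmax(start, 1L), d - target_shape + 1L)
  end <- start + target_shape - 1L
  cropped <- volume$data[start[1]:end[1], start[2]:end[2], start[3]:end[3],
                         drop = FALSE]
  plan <- structure(list(start_index = as.integer(start),
                         target_shape = target_shape,
                         source_shape = as.integer(d)),
                    class = "crop_plan")
  list(volume = volume_grid(cropped, volume$voxel_size_mm, volume$affine),
       plan = plan)
}

#' Undo a crop by zero-padding back to the source grid
#'
#' @param volume the cropped [volume_grid()].
#' @param plan the `crop_plan` returned by [crop_to_foreground()].
#' @return A [volume_grid()] on the original grid.
#' @export
uncrop <- function(volume, plan) {
  stopifnot(is_volume_grid(volume), inherits(plan, "crop_plan"))
  if (!all(dim(volume$data) == plan$target_shape))
    stop("volume shape does not match the crop plan")
  out <- array(0, dim = plan$source_shape)
  s <- plan$start_index
  e <- s + plan$target_shape - 1L
  out[s[1]:e[1], s[2]:e[2], s[3]:e[3]] <- volume$data
  volume_grid(out, volume$voxel_size_mm, volume$affine)
}

#' Proportional global intensity scaling
#'
#' Rescales the volume linearly so that its in-mask mean equals
#' `target_mean`. Following the SPM convention for the "global" value, the
#' mask is the set of voxels above one eighth of the whole-volume mean.
#' Applied to every state entering a voxel-wise comparison so that overall
#' intensity offsets between states cancel.
#'
#' @param volume a [volume_grid()].
#' @param target_mean positive target for the in-mask mean (default 50, an
#'   SPM-like constant; any positive value is equivalent under linear
#'   statistics).
#' @param mask optional explicit binary/logical mask defining the "global"
#'   region. By default the SPM mean/8 rule is used; an explicit anatomy
#'   mask is preferable for generated volumes, whose background is near zero
#'   but not exactly zero and can otherwise flood the mean/8 mask.
#' @return Scaled [volume_grid()].
#' @export
global_scale <- function(volume, target_mean = 50, mask = NULL) {
  stopifnot(is_volume_grid(volume))
  if (!is.numeric(target_mean) || length(target_mean) != 1L ||
      target_mean <= 0)
    stop("`target_mean` must be a positive scalar")
  if (is.null(mask)) {
    g <- global_mean(volume$data)
  } else {
    if (is_volume_grid(mask)) mask <- mask$data
    if (!all(dim(mask) == dim(volume$data)))
      stop("mask shape does not match the volume")
    sel <- as.logical(mask != 0)
    g <- if (any(sel)) mean(volume$data[sel]) else NA_real_
  }
  if (!is.finite(g) || g <= 0)
    stop("degenerate input: in-mask mean is not positive")
  volume$data <- volume$data * (target_mean / g)
  volume
}

global_mean <- function(a) {
  m <- mean(a) / 8
  sel <- a > m
  if (!any(sel)) return(NA_real_)
  mean(a[sel])
}

#' Map volume intensities to and from the network range [-1, 1]
#'
#' Affine map of `[0, data_max]` onto `[-1, 1]` used at the network
#' interface; `data_max` is taken from training-set statistics so the map is
#' shared across subjects.
#'
#' @param volume a [volume_grid()].
#' @param data_max positive scale; should be at least the maximum value
#'   observed in the training set.
#' @return A [volume_grid()].
#' @export
to_network_range <- function(volume, data_max) {
  stopifnot(is_volume_grid(volume))
  if (!is.numeric(data_max) || length(data_max) != 1L || data_max <= 0)
    stop("`data_max` must be a positive scalar")
  volume$data <- 2 * volume$data / data_max - 1
  volume
}

#' @rdname to_network_range
#' @export
from_network_range <- function(volume, data_max) {
  stopifnot(is_volume_grid(volume))
  if (!is.numeric(data_max) || length(data_max) != 1L || data_max <= 0)
    stop("`data_max` must be a positive scalar")
  volume$data <- (volume$data + 1) / 2 * data_max
  volume
}
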