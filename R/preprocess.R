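#' Preprocessing parameters
#'
#' Parameters of the two-track preprocessing that turns one grayscale stack
#' into (a) the skeletonization input and (b) the thickness-measurement
#' input. Defaults are tuned for 8-bit nest CT stacks:
#' a slice-axis averaging filter (sigma 5 slices), a 3D Gaussian blur
#' (sigma 1 voxel) and cutoff 28 for the skeleton track; a 3D Gaussian blur
#' (sigma 2 voxels) and cutoff 24 for the thickness track. Sigmas are in
#' voxel units per axis (the convention of common image-processing software),
#' which matters because the stacks are anisotropic.
#'
#' @param z_sigma_slices sigma of the z-axis averaging filter, in slices.
#' @param gauss_sigma_vox_skel isotropic Gaussian sigma (voxels), skeleton track.
#' @param threshold_skel global threshold (0-255), skeleton track.
#' @param gauss_sigma_vox_thick isotropic Gaussian sigma (voxels), thickness track.
#' @param threshold_thick global threshold (0-255), thickness track.
#' @param z_kernel kernel shape of the z averaging filter: `"gaussian"`
#'   (default) or `"box"`.
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(z_sigma_slices = 5,
                              gauss_sigma_vox_skel = 1,
                              threshold_skel = 28L,
                              gauss_sigma_vox_thick = 2,
                              threshold_thick = 24L,
                              z_kernel = c("gaussian", "box")) {
  z_kernel <- match.arg(z_kernel)
  p <- list(z_sigma_slices = z_sigma_slices,
            gauss_sigma_vox_skel = gauss_sigma_vox_skel,
            threshold_skel = as.integer(threshold_skel),
            gauss_sigma_vox_thick = gauss_sigma_vox_thick,
            threshold_thick = as.integer(threshold_thick),
            z_kernel = z_kernel)
  sig <- c(p$z_sigma_slices, p$gauss_sigma_vox_skel, p$gauss_sigma_vox_thick)
  if (any(!is.finite(sig)) || any(sig < 0)) stop("sigmas must be >= 0")
  thr <- c(p$threshold_skel, p$threshold_thick)
  if (any(thr < 0 | thr > 255)) stop("thresholds must lie in [0, 255]")
  structure(p, class = "preprocess_params")
}

gaussian_kernel <- function(sigma, truncate = 3.5) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  k <- exp(-(((-r):r)^2) / (2 * sigma^2))
  k / sum(k)
}

box_kernel <- function(sigma) {
  # box filter with the same standard deviation: half-width = sigma * sqrt(3)
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(round(sigma * sqrt(3))))
  rep(1 / (2 * r + 1), 2 * r + 1)
}

convolve_axis <- function(v, kernel, axis) {
  d <- dim(v$data)
  out <- convolve_axis_cpp(as.numeric(v$data), d, kernel, axis)
  volume(array(out, dim = d), v$spacing)
}

#' Averaging filter along the slice (z) axis
#'
#' One-dimensional smoothing along z only, sigma in slice units; x and y are
#' untouched. The kernel shape is a package convention: a Gaussian by
#' default, for consistency with the adjacent 3D Gaussian step, with a box
#' kernel of equal standard deviation available via `kernel = "box"`.
#'
#' @param v grayscale [volume].
#' @param sigma_slices sigma in slice units (>= 0; 0 is the identity).
#' @param kernel `"gaussian"` or `"box"`.
#' @return A grayscale [volume] of identical shape and spacing.
#' @export
smooth_z <- function(v, sigma_slices, kernel = c("gaussian", "box")) {
  stopifnot_volume(v, binary = FALSE)
  kernel <- match.arg(kernel)
  if (!is.finite(sigma_slices) || sigma_slices < 0) stop("sigma must be >= 0")
  if (sigma_slices == 0) return(v)
  k <- if (kernel == "gaussian") gaussian_kernel(sigma_slices) else box_kernel(sigma_slices)
  convolve_axis(v, k, 1L)
}

#' Isotropic (in voxel units) 3D Gaussian blur
#'
#' Separable Gaussian smoothing with the same sigma, in voxels, along each
#' axis. Because spacing is anisotropic the physical smoothing lengths
#' differ per axis; this matches the behaviour of voxel-based imaging
#' software and is intentional.
#'
#' @param v grayscale [volume].
#' @param sigma_vox sigma in voxel units (>= 0; 0 is the identity).
#' @return A grayscale [volume] of identical shape and spacing.
#' @export
gaussian_3d <- function(v, sigma_vox) {
  stopifnot_volume(v, binary = FALSE)
  if (!is.finite(sigma_vox) || sigma_vox < 0) stop("sigma must be >= 0")
  if (sigma_vox == 0) return(v)
  k <- gaussian_kernel(sigma_vox)
  for (axis in 1:3) v <- convolve_axis(v, k, axis)
  v
}

#' Global intensity threshold
#'
#' A voxel becomes foreground iff its intensity is greater than or equal to
#' the cutoff (the inclusive-\eqn{\ge} side is a documented convention).
#'
#' @param v grayscale [volume].
#' @param cutoff threshold in `[0, 255]`.
#' @return A binary [volume].
#' @export
global_threshold <- function(v, cutoff) {
  stopifnot_volume(v, binary = FALSE)
  if (!is.finite(cutoff) || cutoff < 0 || cutoff > 255)
    stop("cutoff must lie in [0, 255]")
  volume(array(v$data >= cutoff, dim = dim(v$data)), v$spacing)
}

#' Fill enclosed cavities of a binary volume
#'
#' Every background component (6-connectivity) that is not connected to the
#' volume border becomes foreground; no foreground voxel is ever removed.
#' The fill is three-dimensional, not per-slice: a per-slice fill would
#' close tunnel lumens wherever a slice cuts them obliquely.
#'
#' @param b binary [volume].
#' @return A binary [volume].
#' @export
fill_holes <- function(b) {
  stopifnot_volume(b, binary = TRUE)
  d <- dim(b$data)
  volume(array(fill_holes_cpp(as.logical(b$data), d), dim = d), b$spacing)
}

#' Build the skeletonization input
#'
#' Composition `smooth_z` (sigma 5 slices) -> `gaussian_3d` (sigma 1 voxel)
#' -> `global_threshold` (28) -> `fill_holes`, with parameters taken from a
#' [preprocess_params] object. The filled, thresholded volume is what the
#' thinning step consumes; cavities must be filled or the thinning would
#' produce shell-like artifacts instead of centerlines.
#'
#' @param v grayscale [volume].
#' @param params a [preprocess_params] object.
#' @return A binary [volume].
#' @export
make_skeleton_input <- function(v, params = preprocess_params()) {
  stopifnot_volume(v, binary = FALSE)
  v <- smooth_z(v, params$z_sigma_slices, kernel = params$z_kernel)
  v <- gaussian_3d(v, params$gauss_sigma_vox_skel)
  fill_holes(global_threshold(v, params$threshold_skel))
}

#' Build the thickness-measurement input
#'
#' Composition `gaussian_3d` (sigma 2 voxels) -> `global_threshold` (24).
#' Deliberately no z-averaging and no hole filling: this dataset must
#' preserve true cross-sections for diameter measurement.
#'
#' @param v grayscale [volume].
#' @param params a [preprocess_params] object.
#' @return A binary [volume].
#' @export
make_thickness_input <- function(v, params = preprocess_params()) {
  stopifnot_volume(v, binary = FALSE)
  global_threshold(gaussian_3d(v, params$gauss_sigma_vox_thick),
                   params$threshold_thick)
}
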