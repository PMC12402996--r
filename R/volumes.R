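# Shared-grid volume helpers: mask construction, in-mask vector <-> 3-D
# array conversion, and masked Gaussian smoothing.

#' Build a spherical brain mask on a grid
#'
#' A centred sphere covering roughly 40% of the grid volume stands in for a
#' brain mask on the shared synthetic grid.
#'
#' @param grid_shape integer length-3 grid dimensions.
#' @param radius_frac sphere radius as a fraction of the smallest grid edge.
#' @return logical 3-D array.
#' @export
make_brain_mask <- function(grid_shape, radius_frac = 0.45) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 2L))
  ctr <- (grid_shape + 1) / 2
  r <- radius_frac * min(grid_shape)
  dx <- (seq_len(grid_shape[1]) - ctr[1])^2
  dy <- (seq_len(grid_shape[2]) - ctr[2])^2
  dz <- (seq_len(grid_shape[3]) - ctr[3])^2
  d2 <- outer(outer(dx, dy, "+"), dz, "+")
  array(d2 <= r^2, dim = grid_shape)
}

#' Embed an in-mask voxel vector into a 3-D volume
#'
#' @param values numeric vector, one value per `TRUE` voxel of `mask`.
#' @param mask logical 3-D array.
#' @param fill value for out-of-mask voxels (default `NA`).
#' @return numeric 3-D array.
#' @export
unmask <- function(values, mask, fill = NA_real_) {
  stopifnot(length(values) == sum(mask))
  vol <- array(fill, dim = dim(mask))
  vol[mask] <- values
  vol
}

#' Extract the in-mask voxel vector from a volume
#' @param vol numeric 3-D array.
#' @param mask logical 3-D array of the same shape.
#' @return numeric vector of length `sum(mask)`.
#' @export
mask_values <- function(vol, mask) {
  stopifnot(identical(dim(vol), dim(mask)))
  vol[mask]
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  half <- max(1L, ceiling(4 * sigma_vox))
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# 1-D convolution along axis `along` of a 3-D array, zero-padded.
convolve_axis <- function(vol, kernel, along) {
  if (length(kernel) == 1L) return(vol)
  d <- dim(vol)
  half <- (length(kernel) - 1L) %/% 2L
  perm <- switch(along, c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 1L, 2L))
  v <- aperm(vol, perm)
  m <- matrix(v, nrow = dim(v)[1])
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(kernel)) {
    off <- j - half - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + kernel[j] * m[src[ok], ]
  }
  v <- array(out, dim = dim(v))
  aperm(v, order(perm))
}

#' Gaussian smoothing of a volume, optionally restricted to a mask
#'
#' Separable Gaussian filter with `sd = fwhm / (2 sqrt(2 log 2))` per axis.
#' With a mask, smoothing is renormalised at mask edges by dividing the
#' smoothed masked data by the smoothed mask, so a constant in-mask volume
#' is left unchanged; out-of-mask voxels are `NA`.
#'
#' @param vol numeric 3-D array; `NA` treated as missing (zero weight).
#' @param fwhm_mm full width at half maximum in mm; `0` is the identity.
#' @param voxel_size_mm voxel edge length in mm.
#' @param mask optional logical array; default smooths the full grid.
#' @return numeric 3-D array.
#' @export
smooth_volume <- function(vol, fwhm_mm, voxel_size_mm = 3, mask = NULL) {
  stopifnot(is.array(vol), length(dim(vol)) == 3L)
  if (fwhm_mm < 0) stop("fwhm_mm must be nonnegative")
  if (fwhm_mm == 0) return(vol)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  k <- gaussian_kernel_1d(sigma)
  if (is.null(mask)) mask <- array(TRUE, dim(vol))
  w <- array(as.numeric(mask & !is.na(vol)), dim(vol))
  v <- vol
  v[w == 0] <- 0
  for (ax in 1:3) {
    v <- convolve_axis(v, k, ax)
    w <- convolve_axis(w, k, ax)
  }
  out <- array(NA_real_, dim(vol))
  ok <- mask & w > 1e-12
  out[ok] <- v[ok] / w[ok]
  out
}
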