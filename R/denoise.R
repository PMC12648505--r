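#' Estimate the noise standard deviation of a volume
#'
#' Robust MAD estimate from first differences along z (the difference of two
#' i.i.d. noise samples has standard deviation `sigma * sqrt(2)`).
#'
#' @param volume a `lymph_volume`.
#' @return estimated sigma of the additive noise.
#' @export
estimate_noise_sigma <- function(volume) {
  d <- diff(volume$data[, 1:min(dim(volume$data)[2], 64L),
                        1:min(dim(volume$data)[3], 64L), drop = FALSE])
  stats::mad(as.numeric(d)) / sqrt(2)
}

#' 3D non-local means denoising
#'
#' Plain 3D NLM: each voxel is replaced by a weighted mean of voxels in a
#' search window, weights decaying with the mean squared difference of the
#' surrounding patches, `w = exp(-D / h^2)`.  The parameters are not fixed
#' by the source method; defaults (patch radius 1, search radius 3,
#' `h = 0.8 * sigma` with sigma estimated by robust MAD) are common choices
#' and fully configurable.
#'
#' @param volume a `lymph_volume`.
#' @param patch_radius_vox patch half-width in voxels (>= 1).
#' @param search_radius_vox search half-width in voxels (>= 1).
#' @param h filtering strength; `NULL` derives `0.8 * estimate_noise_sigma()`.
#' @param sigma noise standard deviation used for the noise-bias term
#'   `2 * sigma^2` subtracted from patch distances (Buades' weighting);
#'   `NULL` estimates it by robust MAD.
#' @return the denoised `lymph_volume` (same shape).
#' @export
denoise_nlm3d <- function(volume, patch_radius_vox = 1, search_radius_vox = 3,
                          h = NULL, sigma = NULL) {
  if (patch_radius_vox < 1 || search_radius_vox < 1)
    stop("radii must be >= 1")
  if (is.null(sigma)) sigma <- estimate_noise_sigma(volume)
  if (is.null(h)) {
    h <- 0.8 * sigma
    if (!is.finite(h) || h <= 0) return(volume)  # noiseless input: fixed point
  }
  if (!is.finite(h) || h <= 0) stop("h must be finite and > 0")
  dat <- cpp_nlm3d(as.double(volume$data), dim(volume$data),
                   as.integer(patch_radius_vox), as.integer(search_radius_vox),
                   as.double(h), as.double(sigma))
  volume3d(array(dat, dim(volume$data)), volume$spacing_um, volume$origin_um,
           volume$channel)
}
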