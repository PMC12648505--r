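#' 3D intensity volume with physical voxel spacing
#'
#' The carrier of all image stages.  `data` is an R array with
#' `dim = c(nz, ny, nx)`; `spacing_um` and `origin_um` are `(z, y, x)`
#' triples in micrometers, z being depth below the epidermal surface.
#'
#' @param data 3D numeric array of nonnegative, finite intensities.
#' @param spacing_um positive `(z, y, x)` voxel spacing, um.  A scalar is
#'   recycled.
#' @param origin_um physical offset of the volume corner, um.
#' @param channel free-text channel label.
#' @return an object of class `lymph_volume`.
#' @export
volume3d <- function(data, spacing_um, origin_um = c(0, 0, 0), channel = "") {
  if (length(dim(data)) != 3) stop("data must be a 3D array")
  if (any(dim(data) < 1)) stop("grid must be non-empty")
  if (!all(is.finite(data))) stop("intensities must be finite")
  if (length(spacing_um) == 1) spacing_um <- rep(spacing_um, 3)
  if (length(spacing_um) != 3 || any(!is.finite(spacing_um)) || any(spacing_um <= 0))
    stop("spacing_um must be three positive finite values")
  if (length(origin_um) != 3) stop("origin_um must have length 3")
  structure(list(data = data, spacing_um = as.numeric(spacing_um),
                 origin_um = as.numeric(origin_um), channel = channel),
            class = "lymph_volume")
}

#' Binary segmentation mask
#'
#' Same geometry as its source volume; values are 0/1.
#'
#' @param data 3D array coercible to logical.
#' @param spacing_um,origin_um geometry, as in [volume3d()].
#' @return an object of class `lymph_mask`.
#' @export
seg_mask <- function(data, spacing_um, origin_um = c(0, 0, 0)) {
  if (length(dim(data)) != 3) stop("data must be a 3D array")
  m <- array(as.logical(data), dim = dim(data))
  if (anyNA(m)) stop("mask values must be 0/1")
  if (length(spacing_um) == 1) spacing_um <- rep(spacing_um, 3)
  structure(list(data = m, spacing_um = as.numeric(spacing_um),
                 origin_um = as.numeric(origin_um)),
            class = "lymph_mask")
}

#' @export
#' @method print lymph_volume
print.lymph_volume <- function(x, ...) {
  cat(sprintf("<lymph_volume> %s  dim (z,y,x) = %s  spacing = %s um\n",
              if (nzchar(x$channel)) x$channel else "(unnamed)",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing_um, 4), collapse = ", ")))
  invisible(x)
}

#' @export
#' @method print lymph_mask
print.lymph_mask <- function(x, ...) {
  cat(sprintf("<lymph_mask> dim (z,y,x) = %s  foreground = %d voxels\n",
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

#' Physical volume of one voxel in cubic micrometers
#' @param x a `lymph_volume` or `lymph_mask`.
#' @return scalar um^3.
#' @export
voxel_volume_um3 <- function(x) prod(x$spacing_um)

#' Physical extent of a volume in micrometers
#' @param x a `lymph_volume` or `lymph_mask`.
#' @return `(z, y, x)` extents, um.
#' @export
extent_um <- function(x) dim(x$data) * x$spacing_um

#' Extract a 3D region of interest
#'
#' Returns the sub-volume covering exactly the requested physical region,
#' snapped outward to voxel boundaries (voxel `i` spans
#' `[(i-1)*s, i*s)` relative to the volume origin).
#'
#' @param volume a `lymph_volume`.
#' @param bounds_um 2x3 matrix (rows min,max; columns z,y,x) or list of three
#'   `(min, max)` intervals, in absolute um coordinates.
#' @return the cropped `lymph_volume` with updated `origin_um`.
#' @export
crop_roi <- function(volume, bounds_um) {
  if (is.list(bounds_um)) bounds_um <- sapply(bounds_um, identity)
  b <- matrix(as.numeric(bounds_um), nrow = 2)
  if (ncol(b) != 3) stop("bounds_um must give (min, max) for z, y, x")
  if (any(b[1, ] > b[2, ])) stop("empty ROI bounds: min > max")
  rel <- sweep(b, 2, volume$origin_um)     # bounds relative to volume corner
  ext <- extent_um(volume)
  tol <- 1e-9 * max(ext)
  if (any(rel[1, ] < -tol) || any(rel[2, ] > ext + tol))
    stop("ROI bounds out of range")
  s <- volume$spacing_um
  i0 <- pmax(1L, as.integer(floor(rel[1, ] / s + 1e-9)) + 1L)
  i1 <- pmin(dim(volume$data), as.integer(ceiling(rel[2, ] / s - 1e-9)))
  if (any(i1 < i0)) stop("empty ROI bounds")
  out <- volume$data[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3], drop = FALSE]
  volume3d(out, s, volume$origin_um + (i0 - 1) * s, volume$channel)
}

round_half_away <- function(x) floor(x + 0.5)

#' Resample a volume to isotropic spacing
#'
#' Trilinear interpolation onto an isotropic grid of spacing `target_um`.
#' Each output dimension is `round(extent_um / target_um)`
#' (half-away-from-zero), minimum 1.  A volume already isotropic at the
#' target spacing is returned unchanged.  Constant volumes stay constant.
#'
#' @param volume a `lymph_volume`.
#' @param target_um target voxel size, um (default 1.8).
#' @return the resampled `lymph_volume`.
#' @export
resample_isotropic <- function(volume, target_um = 1.8) {
  if (!is.finite(target_um) || target_um <= 0) stop("target_um must be > 0")
  s <- volume$spacing_um
  if (all(abs(s - target_um) < 1e-9)) return(volume)
  out_dim <- pmax(1L, as.integer(round_half_away(extent_um(volume) / target_um)))
  dat <- cpp_resample_trilinear(as.double(volume$data), dim(volume$data),
                                s, out_dim, rep(target_um, 3))
  volume3d(array(dat, out_dim), rep(target_um, 3), volume$origin_um,
           volume$channel)
}
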