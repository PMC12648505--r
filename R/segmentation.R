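#' Otsu threshold of a volume
#'
#' Histogram-based threshold maximizing between-class variance; used as the
#' data-driven default for the hysteresis high threshold.
#'
#' @param volume a `lymph_volume` (or numeric array/vector).
#' @param n_bins histogram resolution.
#' @return scalar threshold on the intensity scale.
#' @export
otsu_threshold <- function(volume, n_bins = 256) {
  x <- if (inherits(volume, "lymph_volume")) as.numeric(volume$data) else as.numeric(volume)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(n_bins, 1L + as.integer((x - rng[1]) / diff(rng) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  w <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sb <- (mu_t * w - mu)^2 / (w * (1 - w))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

#' Dual-threshold 3D hysteresis segmentation
#'
#' Foreground is the union of connected components of `{I >= t_low}` that
#' contain at least one voxel with `I >= t_high`.  With `t_low == t_high`
#' this reduces to a simple threshold.
#'
#' @param volume a `lymph_volume`.
#' @param t_low,t_high low/high intensity thresholds, `t_low <= t_high`.
#' @param connectivity 6, 18 or 26 (default 26: thin oblique vessels fragment
#'   under 6-connectivity).
#' @return a `lymph_mask`.
#' @export
hysteresis_segment <- function(volume, t_low, t_high, connectivity = 26) {
  if (!is.finite(t_low) || !is.finite(t_high)) stop("thresholds must be finite")
  if (t_low > t_high) stop("t_low must be <= t_high")
  low <- volume$data >= t_low
  lab <- cpp_label_components(low, dim(volume$data), as.integer(connectivity))
  keep_lab <- unique(lab[volume$data >= t_high])
  keep_lab <- keep_lab[keep_lab > 0L]
  m <- array(lab %in% keep_lab, dim = dim(volume$data))
  seg_mask(m, volume$spacing_um, volume$origin_um)
}

#' Discard small connected components
#'
#' Components whose physical volume is strictly less than `min_volume_um3`
#' ("inferior to") are removed; all others are untouched.  At the default
#' configuration and 1.8 um isotropic spacing the threshold corresponds to
#' 1e6 voxels.  Idempotent.
#'
#' @param mask a `lymph_mask`.
#' @param min_volume_um3 minimum component volume, um^3.
#' @param connectivity 6, 18 or 26.
#' @return the filtered `lymph_mask`.
#' @export
filter_components <- function(mask, min_volume_um3, connectivity = 26) {
  lab <- cpp_label_components(mask$data, dim(mask$data), as.integer(connectivity))
  ncc <- attr(lab, "n_components")
  if (ncc == 0L) return(mask)
  counts <- tabulate(lab, nbins = ncc)
  keep <- which(counts * voxel_volume_um3(mask) >= min_volume_um3)
  m <- array(lab %in% keep, dim = dim(mask$data))
  seg_mask(m, mask$spacing_um, mask$origin_um)
}
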