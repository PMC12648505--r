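#' Pipeline configuration
#'
#' Builds the parameter set driving every pipeline stage.  All physical
#' parameters are stored in micrometers so behavior is independent of the
#' acquisition resolution; voxel equivalents are derived at run time (e.g.
#' the component filter of 5.832e6 um^3 corresponds to 1e6 voxels at the
#' default 1.8 um isotropic spacing).  Two parameters are deliberately in
#' voxel units because that is the convention of the methods they feed:
#' `preblur_sigma_vox` (Gaussian blur before adaptive binarization) and
#' `adaptive_window_vox` (local-mean window).
#'
#' @param ... named overrides of the defaults listed below.
#'
#' @details Fields and defaults:
#' \describe{
#'   \item{iso_spacing_um (1.8)}{target isotropic voxel size after resampling.}
#'   \item{t_low, t_high (NA)}{hysteresis thresholds; when `NA` they are
#'     data-driven: `t_high` from Otsu's method on the denoised volume and
#'     `t_low = 0.5 * t_high`.}
#'   \item{min_component_volume_um3 (5.832e6)}{connected components smaller
#'     than this (strict less-than) are discarded as artifacts.}
#'   \item{min_edge_length_um (10)}{minimum graph edge length; shorter spurs
#'     and interior edges are removed/collapsed until convergence.}
#'   \item{border_capillary_max_um (25)}{border-touching elements shorter
#'     than this are discarded as cropped capillaries.}
#'   \item{border_precollector_min_um (300)}{border-touching elements longer
#'     than this are kept as cropped precollectors.}
#'   \item{opening_radius_um (18)}{radius of the spherical structuring
#'     element used for background attenuation before valve detection.}
#'   \item{preblur_sigma_vox (2)}{Gaussian sigma, in voxels, before adaptive
#'     binarization.}
#'   \item{adaptive_sensitivity (0.5)}{sensitivity of the local-mean
#'     adaptive binarization, in `[0, 1]`.}
#'   \item{adaptive_window_vox (NA)}{odd window width in voxels; `NA` derives
#'     `2 * floor(opening_radius_um / spacing) + 1`.}
#'   \item{valve_volume_min_um3, valve_volume_max_um3 (1e3, 1e4)}{volume gate
#'     for acceptable valves.}
#'   \item{valve_floor_mads (6)}{noise floor of the adaptive binarization in
#'     robust-MAD units of the enhanced in-mask signal; 0 restores the pure
#'     relative rule (see the methods vignette).}
#'   \item{junction_radius_um (20)}{distance to a branch-link junction node
#'     within which a valve is classified base-of-capillary.}
#'   \item{layer_z_bands_um (c(150, 210))}{depth boundaries separating the
#'     capillary, precollector and collector network layers.}
#'   \item{connectivity (26)}{voxel neighborhood order (6, 18 or 26).}
#'   \item{denoise (TRUE)}{run NLM denoising before segmentation.}
#'   \item{nlm_patch_radius (1), nlm_search_radius (3), nlm_h (NA)}{NLM
#'     parameters; `NA` sets `h = 0.8 * sigma` with sigma estimated by
#'     robust MAD of z-differences.}
#'   \item{post_smooth_sigma_vox (1)}{light Gaussian applied after NLM as
#'     part of the preconditioning stage; stabilizes the low hysteresis
#'     threshold against residual correlated noise (0 disables).}
#'   \item{flip_z (FALSE)}{set when the stack is oriented epidermis-at-max-z;
#'     depth must increase into the tissue.}
#'   \item{seed (1)}{seed for any stochastic stage.}
#' }
#'
#' @return an object of class `lymph_config` (a validated named list).
#' @export
#' @examples
#' cfg <- pipeline_config(valve_volume_min_um3 = 2000)
#' cfg$valve_volume_max_um3
pipeline_config <- function(...) {
  cfg <- default_config()
  over <- list(...)
  over <- over[!vapply(over, is.null, logical(1))]   # JSON null == keep default
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg <- modifyList(cfg, over)
  }
  validate_config(cfg)
}

default_config <- function() {
  structure(list(
    iso_spacing_um = 1.8,
    t_low = NA_real_,
    t_high = NA_real_,
    min_component_volume_um3 = 5.832e6,
    min_edge_length_um = 10,
    border_capillary_max_um = 25,
    border_precollector_min_um = 300,
    opening_radius_um = 18,
    preblur_sigma_vox = 2,
    adaptive_sensitivity = 0.5,
    adaptive_window_vox = NA_integer_,
    valve_volume_min_um3 = 1e3,
    valve_volume_max_um3 = 1e4,
    valve_floor_mads = 6,
    junction_radius_um = 20,
    layer_z_bands_um = c(150, 210),
    connectivity = 26L,
    denoise = TRUE,
    nlm_patch_radius = 1L,
    nlm_search_radius = 3L,
    nlm_h = NA_real_,
    post_smooth_sigma_vox = 1,
    flip_z = FALSE,
    seed = 1L
  ), class = "lymph_config")
}

#' Validate a pipeline configuration
#'
#' Checks the cross-field invariants and errors naming the offending field.
#'
#' @param cfg a `lymph_config` or plain named list.
#' @return the validated `lymph_config`, invisibly usable in pipelines.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!isTRUE(ok)) stop("invalid config field '", field, "': ", why, call. = FALSE)
  }
  # normalize storage types so serialization round-trips to an equal object
  for (f in c("iso_spacing_um", "t_low", "t_high", "min_component_volume_um3",
              "min_edge_length_um", "border_capillary_max_um",
              "border_precollector_min_um", "opening_radius_um",
              "preblur_sigma_vox", "adaptive_sensitivity",
              "valve_volume_min_um3", "valve_volume_max_um3",
              "valve_floor_mads", "junction_radius_um", "layer_z_bands_um",
              "nlm_h", "post_smooth_sigma_vox"))
    cfg[[f]] <- as.numeric(cfg[[f]])
  for (f in c("connectivity", "nlm_patch_radius", "nlm_search_radius", "seed"))
    cfg[[f]] <- as.integer(cfg[[f]])
  if (!is.na(cfg$adaptive_window_vox))
    cfg$adaptive_window_vox <- as.integer(cfg$adaptive_window_vox)
  for (f in c("denoise", "flip_z")) cfg[[f]] <- as.logical(cfg[[f]])
  pos <- c("iso_spacing_um", "min_component_volume_um3", "min_edge_length_um",
           "border_capillary_max_um", "border_precollector_min_um",
           "opening_radius_um", "preblur_sigma_vox", "valve_volume_min_um3",
           "valve_volume_max_um3", "junction_radius_um")
  for (f in pos) chk(is.numeric(cfg[[f]]) && all(cfg[[f]] > 0), f, "must be > 0")
  if (!is.na(cfg$t_low) && !is.na(cfg$t_high))
    chk(cfg$t_low <= cfg$t_high, "t_low", "t_low must be <= t_high")
  chk(cfg$valve_volume_min_um3 < cfg$valve_volume_max_um3,
      "valve_volume_min_um3", "must be < valve_volume_max_um3")
  chk(cfg$border_capillary_max_um < cfg$border_precollector_min_um,
      "border_capillary_max_um", "must be < border_precollector_min_um")
  chk(cfg$adaptive_sensitivity >= 0 && cfg$adaptive_sensitivity <= 1,
      "adaptive_sensitivity", "must be in [0, 1]")
  chk(cfg$valve_floor_mads >= 0, "valve_floor_mads", "must be >= 0")
  chk(cfg$post_smooth_sigma_vox >= 0, "post_smooth_sigma_vox", "must be >= 0")
  if (!is.na(cfg$adaptive_window_vox))
    chk(cfg$adaptive_window_vox >= 3 && cfg$adaptive_window_vox %% 2 == 1,
        "adaptive_window_vox", "must be an odd integer >= 3")
  chk(cfg$connectivity %in% c(6L, 18L, 26L), "connectivity", "must be 6, 18 or 26")
  chk(length(cfg$layer_z_bands_um) >= 1 &&
        !is.unsorted(cfg$layer_z_bands_um, strictly = TRUE),
      "layer_z_bands_um", "must be strictly increasing")
  structure(cfg, class = "lymph_config")
}

#' Read a configuration from a JSON file
#'
#' Absent keys keep their defaults; an empty file yields the full default
#' configuration.  Invariant violations are rejected with the offending
#' field named.
#'
#' @param path path to a JSON document of config fields.
#' @return a `lymph_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!nzchar(trimws(txt))) return(pipeline_config())
  vals <- tryCatch(jsonlite::fromJSON(txt),
                   error = function(e) stop("malformed config file: ",
                                            conditionMessage(e), call. = FALSE))
  if (!is.list(vals) || (length(vals) && is.null(names(vals))))
    stop("malformed config file: expected a JSON object")
  do.call(pipeline_config, vals)
}

#' Write a configuration to a JSON file
#'
#' `load_config(save_config(cfg, path))` round-trips to an equal config.
#'
#' @param cfg a `lymph_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' MD5 hash of a configuration (artifact provenance)
#' @param cfg a `lymph_config`.
#' @return a 32-character md5 string.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  save_config(cfg, tf)
  unname(tools::md5sum(tf))
}

#' @export
#' @method print lymph_config
print.lymph_config <- function(x, ...) {
  cat("<lymph_config>\n")
  for (f in names(x))
    cat(sprintf("  %-26s %s\n", f, paste(format(x[[f]]), collapse = ", ")))
  invisible(x)
}
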