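#' Run the full quantification pipeline
#'
#' Stage order: (optional ROI crop) -> isotropic resampling -> NLM
#' denoising -> dual-threshold hysteresis segmentation -> small-component
#' filter -> skeletonization -> graph conversion (with convergence) ->
#' edge classification, border rules and layer assignment -> background
#' attenuation + valve detection -> valve classification -> metrics.  One
#' structured log line per stage (duration, input/output counts).  All
#' randomness is controlled by `config$seed`; a fixed seed reproduces
#' byte-identical artifacts.
#'
#' @param input a `lymph_volume` or a TIFF path.
#' @param config a `lymph_config` (default [pipeline_config()]).
#' @param out_dir optional artifact directory (mask TIFF, graph CSV +
#'   GraphML, valve CSV, metrics JSON/CSV, resolved config); every artifact
#'   carries the config md5 hash.
#' @param channel2 optional co-registered second channel (`lymph_volume` or
#'   path) for [intensity_by_valve_position()].
#' @param roi_bounds_um optional crop applied before resampling.
#' @param dry_run print the resolved configuration and return it without
#'   touching anything.
#' @param verbose emit per-stage log lines (default TRUE).
#' @return an object of class `lymph_result`: `volume` (preprocessed),
#'   `mask`, `graph`, `valves`, `metrics`, `thresholds`, `config`, `log`.
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir = NULL,
                         channel2 = NULL, roi_bounds_um = NULL,
                         dry_run = FALSE, verbose = TRUE) {
  config <- validate_config(config)
  if (dry_run) {
    print(config)
    return(invisible(config))
  }
  set.seed(config$seed)
  log <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, detail) {
    if (verbose) message(sprintf("[%s] %s", name, detail))
    log[[name]] <<- detail
  }
  t0 <- tic()
  vol <- if (is.character(input)) read_volume(input) else input
  if (!inherits(vol, "lymph_volume")) stop("stage input: need a lymph_volume or path")
  if (isTRUE(config$flip_z)) vol$data <- vol$data[rev(seq_len(dim(vol$data)[1])), , ]
  if (!is.null(roi_bounds_um)) vol <- crop_roi(vol, roi_bounds_um)
  stage("input", sprintf("dim %s, spacing %s um (%.1fs)",
                         paste(dim(vol$data), collapse = "x"),
                         paste(signif(vol$spacing_um, 3), collapse = ","),
                         tic() - t0))

  t0 <- tic()
  vol <- resample_isotropic(vol, config$iso_spacing_um)
  stage("resample", sprintf("dim %s at %.3g um (%.1fs)",
                            paste(dim(vol$data), collapse = "x"),
                            config$iso_spacing_um, tic() - t0))

  if (isTRUE(config$denoise)) {
    t0 <- tic()
    h <- if (is.na(config$nlm_h)) NULL else config$nlm_h
    vol <- denoise_nlm3d(vol, config$nlm_patch_radius,
                         config$nlm_search_radius, h)
    if (config$post_smooth_sigma_vox > 0)
      vol$data <- array(cpp_gauss3d(as.double(vol$data), dim(vol$data),
                                    rep(config$post_smooth_sigma_vox, 3)),
                        dim(vol$data))
    stage("denoise", sprintf("nlm patch %d search %d + smooth %.2g vox (%.1fs)",
                             config$nlm_patch_radius, config$nlm_search_radius,
                             config$post_smooth_sigma_vox, tic() - t0))
  }

  t0 <- tic()
  t_high <- if (is.na(config$t_high)) otsu_threshold(vol) else config$t_high
  t_low <- if (is.na(config$t_low)) 0.5 * t_high else config$t_low
  mask <- hysteresis_segment(vol, t_low, t_high, config$connectivity)
  n_before <- sum(mask$data)
  mask <- filter_components(mask, config$min_component_volume_um3,
                            config$connectivity)
  stage("segment", sprintf("t_low %.3g t_high %.3g; %d -> %d voxels (%.1fs)",
                           t_low, t_high, n_before, sum(mask$data), tic() - t0))

  t0 <- tic()
  skel <- skeletonize(mask)
  graph <- skeleton_to_graph(skel, config$min_edge_length_um, prune_mask = mask)
  graph <- classify_edges(graph)
  graph <- apply_border_rules(graph, NULL, config$border_capillary_max_um,
                              config$border_precollector_min_um, mask = mask)
  graph <- assign_layers(graph, config$layer_z_bands_um)
  stage("graph", sprintf("%d skeleton voxels -> %d nodes, %d edges (%.1fs)",
                         nrow(skel$coords), nrow(graph$nodes),
                         nrow(graph$edges), tic() - t0))

  t0 <- tic()
  enhanced <- attenuate_background(vol, mask, config$opening_radius_um)
  win <- if (is.na(config$adaptive_window_vox))
    2L * as.integer(config$opening_radius_um / config$iso_spacing_um) + 1L
  else as.integer(config$adaptive_window_vox)
  valves <- detect_valve_blobs(enhanced, mask, config$preblur_sigma_vox,
                               config$adaptive_sensitivity, win,
                               c(config$valve_volume_min_um3,
                                 config$valve_volume_max_um3),
                               config$valve_floor_mads)
  valves <- classify_valve_positions(valves, graph, config$junction_radius_um)
  valves <- assign_layers(valves, config$layer_z_bands_um)
  stage("valves", sprintf("%d valves detected (%.1fs)", nrow(valves), tic() - t0))

  t0 <- tic()
  ch2 <- if (is.character(channel2)) read_volume(channel2) else channel2
  metrics <- compile_metrics(mask, graph, valves, channel2 = ch2)
  stage("metrics", sprintf("volume density %.3g, %d valves (%.1fs)",
                           metrics$volume_density, metrics$n_valves, tic() - t0))

  res <- structure(list(volume = vol, mask = mask, graph = graph,
                        valves = valves, metrics = metrics,
                        thresholds = c(t_low = t_low, t_high = t_high),
                        config = config, log = log),
                   class = "lymph_result")
  if (!is.null(out_dir)) write_result(res, out_dir)
  res
}

#' @export
#' @method print lymph_result
print.lymph_result <- function(x, ...) {
  cat("<lymph_result>\n")
  print(x$metrics)
  invisible(x)
}

#' Write all pipeline artifacts
#' @param result a `lymph_result`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- config_hash(result$config)
  save_config(result$config, file.path(out_dir, "config.json"))
  write_volume(result$mask, file.path(out_dir, "mask.tif"), "uint8",
               config_md5 = h)
  write_graph_csv(result$graph, file.path(out_dir, "graph"), config_md5 = h)
  write_graphml(result$graph, file.path(out_dir, "graph.graphml"))
  write_valves_csv(result$valves, file.path(out_dir, "valves.csv"),
                   config_md5 = h)
  write_metrics(result$metrics, out_dir, config_md5 = h)
  invisible(out_dir)
}
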