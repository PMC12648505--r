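#' Network volume and length density
#'
#' Volume density is the foreground fraction (volume of network / volume of
#' sample, unitless); length density is the summed length of retained
#' (non-discarded) graph edges per sample volume, reported both in um/um^3
#' and mm/mm^3 (`mm_per_mm3 = 1e6 * um_per_um3`).
#'
#' @param mask the network `lymph_mask`.
#' @param graph the classified `lymph_graph` from the same ROI.
#' @param sample_volume_um3 physical sample volume; defaults to the mask
#'   grid volume.
#' @return list with `volume_density`, `length_density_um_per_um3`,
#'   `length_density_mm_per_mm3`.
#' @export
network_density <- function(mask, graph, sample_volume_um3 = NULL) {
  if (is.null(sample_volume_um3))
    sample_volume_um3 <- prod(extent_um(mask))
  if (!is.finite(sample_volume_um3) || sample_volume_um3 <= 0)
    stop("sample volume must be > 0")
  keep <- retained_edges(graph)
  total_len <- sum(graph$edges$length_um[keep])
  list(volume_density = sum(mask$data) * voxel_volume_um3(mask) / sample_volume_um3,
       length_density_um_per_um3 = total_len / sample_volume_um3,
       length_density_mm_per_mm3 = 1e6 * total_len / sample_volume_um3)
}

retained_edges <- function(graph) {
  cls <- graph$edges$class
  which(is.na(cls) | cls != "discarded")
}

#' Per-capillary statistics
#'
#' One record per `capillary_branch` edge: polyline length and the minimum
#' and maximum depth of its path.  Discarded and border-ambiguous edges are
#' excluded.
#'
#' @param graph a classified `lymph_graph`.
#' @return data.frame with `edge_id`, `length_um`, `z_min_um`, `z_max_um`.
#' @export
capillary_stats <- function(graph) {
  sel <- which(graph$edges$class %in% "capillary_branch")
  data.frame(edge_id = graph$edges$id[sel],
             length_um = graph$edges$length_um[sel],
             z_min_um = vapply(graph$paths[sel], function(p) min(p[, 1]), numeric(1)),
             z_max_um = vapply(graph$paths[sel], function(p) max(p[, 1]), numeric(1)))
}

#' 3D orientation of a capillary path
#'
#' Orientation of the ellipsoid with the same normalized second central
#' moments as the path: the principal axis `v` (unit eigenvector of the
#' largest eigenvalue of the covariance of the path's physical
#' coordinates), sign-fixed to `v_z >= 0`, interpreted by looking at the
#' origin along the x-, y- and z-axes:
#' `roll = atan2(v_y, v_z)`, `pitch = atan2(v_x, v_z)`,
#' `yaw = atan2(v_y, v_x)`; a component whose both arguments are 0 is
#' defined as 0.  Angles in degrees, range (-180, 180].
#'
#' @param path_um n x 3 matrix of (z, y, x) physical coordinates, or an
#'   n x 3 voxel-coordinate matrix together with `spacing_um`.
#' @param spacing_um optional (z, y, x) spacing to scale voxel coordinates.
#' @return named numeric vector `c(roll_deg, pitch_deg, yaw_deg)`.
#' @export
capillary_orientation <- function(path_um, spacing_um = NULL) {
  p <- as.matrix(path_um)
  if (!is.null(spacing_um)) p <- sweep(p, 2, spacing_um, `*`)
  if (nrow(p) < 2) stop("orientation needs at least 2 points")
  cm <- sweep(p, 2, colMeans(p))
  ev <- eigen(crossprod(cm) / nrow(p), symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (v[1] < 0) v <- -v                      # sign fix: v_z >= 0
  at2 <- function(a, b) if (a == 0 && b == 0) 0 else atan2(a, b) * 180 / pi
  c(roll_deg = at2(v[2], v[1]), pitch_deg = at2(v[3], v[1]),
    yaw_deg = at2(v[2], v[3]))
}

#' Cumulative length and range of an ordered multipoint annotation
#'
#' Length is the sum of Euclidean distances between consecutive points,
#' accounting for the voxel dimensions on every axis; range is the
#' Euclidean distance between the first and last points.  A single point
#' yields `(0, 0)`.
#'
#' @param points n x 3 matrix of ordered (z, y, x) voxel coordinates.
#' @param spacing_um (z, y, x) voxel dimensions, um (scalar recycled).
#' @return named numeric vector `c(length_um, range_um)`.
#' @export
multipoint_length <- function(points, spacing_um = c(1, 1, 1)) {
  p <- matrix(as.numeric(points), ncol = 3)
  if (nrow(p) == 0) stop("empty point list")
  if (length(spacing_um) == 1) spacing_um <- rep(spacing_um, 3)
  pu <- sweep(p, 2, spacing_um, `*`)
  if (nrow(pu) == 1) return(c(length_um = 0, range_um = 0))
  c(length_um = sum(sqrt(rowSums(diff(pu)^2))),
    range_um = sqrt(sum((pu[nrow(pu), ] - pu[1, ])^2)))
}

#' Valve counts per network layer
#'
#' Per layer: valve count, summed retained edge length, valves per unit
#' length, and valves per sample mm^3.
#'
#' @param valves layer-assigned valve table.
#' @param graph layer-assigned `lymph_graph`.
#' @param sample_volume_um3 physical sample volume (for the per-mm^3 rate).
#' @param n_layers number of layers (default 3).
#' @return data.frame, one row per layer.
#' @export
valves_per_layer <- function(valves, graph, sample_volume_um3, n_layers = 3) {
  keep <- retained_edges(graph)
  lay_e <- graph$edges$layer[keep]
  len_e <- graph$edges$length_um[keep]
  assigned <- valves[!is.na(valves$layer) & valves$position_class != "unassigned", ,
                     drop = FALSE]
  data.frame(
    layer = seq_len(n_layers),
    n_valves = vapply(seq_len(n_layers), function(l)
      sum(assigned$layer == l), integer(1)),
    length_um = vapply(seq_len(n_layers), function(l)
      sum(len_e[!is.na(lay_e) & lay_e == l]), numeric(1)),
    valves_per_mm = vapply(seq_len(n_layers), function(l) {
      L <- sum(len_e[!is.na(lay_e) & lay_e == l])
      if (L > 0) sum(assigned$layer == l) / (L / 1e3) else 0
    }, numeric(1)),
    valves_per_mm3 = vapply(seq_len(n_layers), function(l)
      sum(assigned$layer == l) / (sample_volume_um3 / 1e9), numeric(1)))
}

#' Inter-valve distances along the network
#'
#' For every edge carrying at least two valves, the valves are ordered by
#' the arc length of their projection onto the edge path and consecutive
#' arc-length differences (distance along the skeleton path) are returned.
#'
#' @param valves edge-assigned valve table (columns `edge_id`, `arc_um`).
#' @param graph the `lymph_graph` (unused beyond validation; distances come
#'   from the projections already stored on the valves).
#' @return numeric vector of distances, um (possibly empty).
#' @export
intervalve_distances <- function(valves, graph) {
  v <- valves[!is.na(valves$edge_id) & !is.na(valves$arc_um), , drop = FALSE]
  if (!nrow(v)) return(numeric(0))
  out <- numeric(0)
  for (e in unique(v$edge_id)) {
    a <- sort(v$arc_um[v$edge_id == e])
    if (length(a) >= 2) out <- c(out, diff(a))
  }
  out
}

#' Second-channel intensity up/downstream of base-of-capillary valves
#'
#' For each `base_of_capillary` valve, the mean channel-2 intensity over
#' in-mask path voxels within `window_um` of the junction node along the
#' capillary side (upstream) and along the precollector-link side
#' (downstream).  The 50 um window is a package choice (the source method
#' does not describe one) and is configurable.
#'
#' @param channel2 co-registered second-channel `lymph_volume`.
#' @param mask network `lymph_mask`.
#' @param graph classified `lymph_graph` with voxel paths.
#' @param valves classified valve table.
#' @param window_um sampling window along the path (default 50).
#' @return data.frame with `valve_id`, `upstream_mean`, `downstream_mean`.
#' @export
intensity_by_valve_position <- function(channel2, mask, graph, valves,
                                        window_um = 50) {
  if (is.null(channel2)) {
    warning("channel 2 missing; intensity_by_valve_position skipped")
    return(data.frame(valve_id = integer(0), upstream_mean = numeric(0),
                      downstream_mean = numeric(0)))
  }
  sel <- which(valves$position_class == "base_of_capillary")
  out <- data.frame(valve_id = valves$id[sel],
                    upstream_mean = NA_real_, downstream_mean = NA_real_)
  if (!length(sel)) return(out)
  cls <- graph$edges$class
  node_pos <- as.matrix(graph$nodes[, c("z_um", "y_um", "x_um")])
  for (k in seq_along(sel)) {
    v <- valves[sel[k], ]
    # junction node: nearest node incident to both a branch and a link
    has_cap <- has_link <- rep(FALSE, nrow(graph$nodes))
    for (j in which(cls %in% "capillary_branch"))
      has_cap[c(graph$edges$from[j], graph$edges$to[j])] <- TRUE
    for (j in which(cls %in% c("precollector_link", "cropped_precollector",
                               "border_ambiguous")))
      has_link[c(graph$edges$from[j], graph$edges$to[j])] <- TRUE
    jn <- which(has_cap & has_link)
    if (!length(jn)) next
    d <- sqrt(rowSums(sweep(node_pos[jn, , drop = FALSE], 2,
                            c(v$z_um, v$y_um, v$x_um))^2))
    node <- jn[which.min(d)]
    up <- path_window_mean(channel2, mask, graph, node, "capillary_branch",
                           window_um)
    dn <- path_window_mean(channel2, mask, graph, node,
                           c("precollector_link", "cropped_precollector",
                             "border_ambiguous"), window_um)
    out$upstream_mean[k] <- up
    out$downstream_mean[k] <- dn
  }
  out
}

path_window_mean <- function(channel2, mask, graph, node, classes, window_um) {
  vals <- numeric(0)
  for (j in which(graph$edges$class %in% classes &
                  (graph$edges$from == node | graph$edges$to == node))) {
    p <- graph$paths[[j]]
    if (graph$edges$from[j] != node) p <- p[nrow(p):1, , drop = FALSE]
    arc <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
    p <- p[arc <= window_um, , drop = FALSE]
    cc <- round(sweep(sweep(p, 2, channel2$origin_um), 2,
                      channel2$spacing_um, `/`) + 0.5)
    cc <- pmax(pmin(cc, matrix(dim(channel2$data), nrow(cc), 3, byrow = TRUE)), 1)
    idx <- vox_index(cc, dim(channel2$data))
    idx <- idx[mask$data[idx]]
    vals <- c(vals, channel2$data[idx])
  }
  if (length(vals)) mean(vals) else NA_real_
}

#' Compile the full metrics report
#'
#' Gathers every morphometric output in one object: densities, capillary
#' statistics and orientations, layer tables, inter-valve distances, valve
#' position fractions and (optionally) channel-2 intensities.
#'
#' @param mask network `lymph_mask`.
#' @param graph classified, layer-assigned `lymph_graph`.
#' @param valves classified, layer-assigned valve table.
#' @param sample_volume_um3 sample volume; defaults to the mask grid volume.
#' @param channel2 optional second channel for
#'   [intensity_by_valve_position()].
#' @return an object of class `lymph_metrics`.
#' @export
compile_metrics <- function(mask, graph, valves, sample_volume_um3 = NULL,
                            channel2 = NULL) {
  if (is.null(sample_volume_um3)) sample_volume_um3 <- prod(extent_um(mask))
  dens <- network_density(mask, graph, sample_volume_um3)
  caps <- capillary_stats(graph)
  ori <- if (nrow(caps)) t(vapply(
    graph$paths[match(caps$edge_id, graph$edges$id)],
    capillary_orientation, numeric(3))) else
      matrix(numeric(0), 0, 3, dimnames = list(NULL, c("roll_deg", "pitch_deg", "yaw_deg")))
  keep <- retained_edges(graph)
  cap_len <- sum(graph$edges$length_um[graph$edges$class %in% "capillary_branch"])
  tot_len <- sum(graph$edges$length_um[keep])
  assigned <- valves$position_class != "unassigned"
  pos_frac <- if (any(assigned)) {
    tb <- table(valves$position_class[assigned])
    as.list(tb / sum(tb))
  } else list()
  structure(list(
    sample_volume_um3 = sample_volume_um3,
    volume_density = dens$volume_density,
    length_density_mm_per_mm3 = dens$length_density_mm_per_mm3,
    capillary_length_fraction = if (tot_len > 0) cap_len / tot_len else 0,
    capillary_lengths_um = caps$length_um,
    capillary_z_range_um = caps[, c("edge_id", "z_min_um", "z_max_um")],
    orientations_deg = ori,
    n_valves = nrow(valves),
    valve_density_per_mm3 = nrow(valves) / (sample_volume_um3 / 1e9),
    valves_per_layer = valves_per_layer(valves, graph, sample_volume_um3),
    intervalve_distances_um = intervalve_distances(valves, graph),
    valve_position_fractions = pos_frac,
    intensity_by_valve_position =
      if (!is.null(channel2))
        intensity_by_valve_position(channel2, mask, graph, valves) else NULL
  ), class = "lymph_metrics")
}

#' @export
#' @method print lymph_metrics
print.lymph_metrics <- function(x, ...) {
  cat("<lymph_metrics>\n")
  cat(sprintf("  volume density            %.4g\n", x$volume_density))
  cat(sprintf("  length density            %.4g mm/mm^3\n",
              x$length_density_mm_per_mm3))
  cat(sprintf("  capillary length fraction %.3f\n", x$capillary_length_fraction))
  cat(sprintf("  valves                    %d (%.1f / mm^3)\n", x$n_valves,
              x$valve_density_per_mm3))
  if (length(x$intervalve_distances_um))
    cat(sprintf("  inter-valve distance      median %.1f um (n = %d)\n",
                stats::median(x$intervalve_distances_um),
                length(x$intervalve_distances_um)))
  invisible(x)
}

#' Write a metrics report to disk
#'
#' One JSON summary plus tidy CSV tables (capillaries, orientations, layer
#' table, inter-valve distances).
#'
#' @param metrics a `lymph_metrics`.
#' @param dir output directory (created if needed).
#' @param config_md5 optional provenance hash embedded in every artifact.
#' @return `dir`, invisibly.
#' @export
write_metrics <- function(metrics, dir, config_md5 = NA_character_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summ <- list(config_md5 = config_md5,
               sample_volume_um3 = metrics$sample_volume_um3,
               volume_density = metrics$volume_density,
               length_density_mm_per_mm3 = metrics$length_density_mm_per_mm3,
               capillary_length_fraction = metrics$capillary_length_fraction,
               n_valves = metrics$n_valves,
               valve_density_per_mm3 = metrics$valve_density_per_mm3,
               valve_position_fractions = metrics$valve_position_fractions,
               median_intervalve_um =
                 if (length(metrics$intervalve_distances_um))
                   stats::median(metrics$intervalve_distances_um) else NA)
  jsonlite::write_json(summ, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  caps <- data.frame(length_um = metrics$capillary_lengths_um)
  if (nrow(metrics$orientations_deg) == nrow(caps))
    caps <- cbind(metrics$capillary_z_range_um, caps, metrics$orientations_deg)
  caps$config_md5 <- config_md5
  write.csv(caps, file.path(dir, "capillaries.csv"), row.names = FALSE)
  lt <- metrics$valves_per_layer; lt$config_md5 <- config_md5
  write.csv(lt, file.path(dir, "valves_per_layer.csv"), row.names = FALSE)
  iv <- data.frame(distance_um = metrics$intervalve_distances_um,
                   config_md5 = if (length(metrics$intervalve_distances_um))
                     config_md5 else character(0))
  write.csv(iv, file.path(dir, "intervalve_distances.csv"), row.names = FALSE)
  invisible(dir)
}
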