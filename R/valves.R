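#' Attenuate residual background inside the network mask (white top-hat)
#'
#' Valves are compact bright blobs (equivalent sphere radius at most ~13.4
#' um for the 1e4 um^3 volume gate), so an opening with an 18 um ball
#' removes them while reproducing every larger structure -- the vessel tube
#' signal itself and slowly varying background.  The opening is therefore
#' the background estimate and the returned image is the masked intensity
#' minus its opening (white top-hat), clipped at zero, with voxels outside
#' the mask set to zero.
#'
#' @param volume a `lymph_volume` (typically the denoised channel).
#' @param mask the network `lymph_mask`.
#' @param radius_um radius of the spherical structuring element (default 18).
#' @return a `lymph_volume` of background-attenuated intensities.
#' @export
attenuate_background <- function(volume, mask, radius_um = 18) {
  if (!identical(dim(volume$data), dim(mask$data)))
    stop("mask not aligned with volume")
  rvox <- as.integer(round(radius_um / volume$spacing_um))
  if (any(rvox < 1)) stop("opening radius smaller than one voxel")
  masked <- volume$data * mask$data
  er <- cpp_morph_ball(as.double(masked), dim(masked), rvox, TRUE)
  op <- cpp_morph_ball(er, dim(masked), rvox, FALSE)
  out <- pmax(masked - op, 0) * mask$data
  volume3d(array(out, dim(masked)), volume$spacing_um, volume$origin_um,
           volume$channel)
}

#' Detect intraluminal valves as bright compact blobs
#'
#' Pipeline: Gaussian blur (`sigma_vox` voxels) -> local-mean adaptive
#' binarization (foreground iff `I > max(mu_local * 2 * (1 - s), floor)`,
#' which at the default sensitivity `s = 0.5` is the plain local mean;
#' window mean via integral images) -> restriction to the network mask ->
#' 26-connected components -> volume gate: only components with
#' `vol_bounds_um3[1] <= volume <= vol_bounds_um3[2]` are acceptable
#' valves.  `floor` is a noise floor of `floor_mads` robust MADs of the
#' in-mask enhanced signal; it is exactly 0 on noise-free input (see the
#' methods vignette for why a purely relative threshold degenerates on
#' masked, zero-background images).
#'
#' @param enhanced output of [attenuate_background()].
#' @param mask the network `lymph_mask`.
#' @param sigma_vox Gaussian sigma in voxels (default 2).
#' @param sensitivity adaptive sensitivity in `[0, 1]` (default 0.5).
#' @param window_vox odd local-mean window width; default
#'   `2 * floor(18 / spacing) + 1` (matched to the structuring scale).
#' @param vol_bounds_um3 acceptable valve volume range (default 1e3..1e4).
#' @param floor_mads noise floor in MAD units (default 6; 0 disables).
#' @return a data.frame of valves: intensity-weighted centroid (um),
#'   volume (um^3), voxel count, and placeholders for position class,
#'   layer and edge assignment.
#' @export
detect_valve_blobs <- function(enhanced, mask, sigma_vox = 2, sensitivity = 0.5,
                               window_vox = NULL, vol_bounds_um3 = c(1e3, 1e4),
                               floor_mads = 6) {
  if (sensitivity < 0 || sensitivity > 1) stop("sensitivity must be in [0, 1]")
  dims <- dim(enhanced$data)
  if (is.null(window_vox))
    window_vox <- 2L * as.integer(18 / min(enhanced$spacing_um)) + 1L
  r <- as.integer((window_vox - 1) / 2)
  blur <- if (sigma_vox > 0)
    cpp_gauss3d(as.double(enhanced$data), dims, rep(sigma_vox, 3))
  else as.double(enhanced$data)
  mu <- cpp_boxmean3d(blur, dims, rep(r, 3L))
  thr <- mu * (2 * (1 - sensitivity))
  if (floor_mads > 0) {
    inm <- enhanced$data[mask$data]
    fl <- floor_mads * stats::mad(inm, center = stats::median(inm))
    thr <- pmax(thr, fl)
  }
  fg <- array(blur > thr, dims) & mask$data
  lab <- cpp_label_components(fg, dims, 26L)
  ncc <- attr(lab, "n_components")
  empty <- valve_table(0)
  if (ncc == 0L) return(empty)
  counts <- tabulate(lab, nbins = ncc)
  vx <- voxel_volume_um3(enhanced)
  keep <- which(counts * vx >= vol_bounds_um3[1] & counts * vx <= vol_bounds_um3[2])
  if (!length(keep)) return(empty)
  sel <- which(lab > 0L & lab %in% keep)
  cl <- match(lab[sel], keep)
  w <- blur[sel]
  cc <- vox_coords(sel, dims)
  um <- vox_um(cc, enhanced$spacing_um, enhanced$origin_um)
  wsum <- tapply(w, cl, sum)
  out <- valve_table(length(keep))
  out$z_um <- as.numeric(tapply(w * um[, 1], cl, sum) / wsum)
  out$y_um <- as.numeric(tapply(w * um[, 2], cl, sum) / wsum)
  out$x_um <- as.numeric(tapply(w * um[, 3], cl, sum) / wsum)
  out$voxel_count <- as.integer(counts[keep])
  out$volume_um3 <- counts[keep] * vx
  out$id <- order(order(out$z_um, out$y_um, out$x_um))  # stable deterministic ids
  out <- out[order(out$id), ]
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

valve_table <- function(n) {
  data.frame(id = seq_len(n), z_um = numeric(n), y_um = numeric(n),
             x_um = numeric(n), volume_um3 = numeric(n),
             voxel_count = integer(n),
             position_class = rep("unassigned", n),
             layer = rep(NA_integer_, n),
             edge_id = rep(NA_integer_, n),
             distance_to_edge_um = rep(NA_real_, n),
             arc_um = rep(NA_real_, n))
}

#' Classify valve positions within the network
#'
#' Each valve is assigned to the edge minimizing the point-to-path distance.
#' Position class: `base_of_capillary` if the valve lies within
#' `junction_radius_um` of a node joining a capillary branch to a
#' precollector link; otherwise `within_capillary` on capillary branches,
#' `precollector` on other edges (`collector` when the edge's layer is 3);
#' `unassigned` when farther than `2 * junction_radius_um` from every edge.
#'
#' @param valves data.frame from [detect_valve_blobs()].
#' @param graph a classified (and layer-assigned, for collector calls)
#'   `lymph_graph`.
#' @param junction_radius_um junction proximity radius (default 20).
#' @return the valve table with `position_class`, `edge_id`,
#'   `distance_to_edge_um` and `arc_um` filled in.
#' @export
classify_valve_positions <- function(valves, graph, junction_radius_um = 20) {
  if (!nrow(valves)) return(valves)
  live <- which(is.na(graph$edges$class) | graph$edges$class != "discarded")
  if (!nrow(graph$edges) || !length(live)) {
    valves$position_class <- "unassigned"
    return(valves)
  }
  pts <- as.matrix(valves[, c("z_um", "y_um", "x_um")])
  # arc-length tables per edge
  arcs <- lapply(graph$paths[live], function(p)
    c(0, cumsum(sqrt(rowSums(diff(p)^2)))))
  best_d <- rep(Inf, nrow(valves)); best_e <- rep(NA_integer_, nrow(valves))
  best_arc <- rep(NA_real_, nrow(valves))
  for (k in seq_along(live)) {
    p <- graph$paths[[live[k]]]
    for (v in seq_len(nrow(valves))) {
      d2 <- (p[, 1] - pts[v, 1])^2 + (p[, 2] - pts[v, 2])^2 + (p[, 3] - pts[v, 3])^2
      j <- which.min(d2)
      d <- sqrt(d2[j])
      if (d < best_d[v]) {
        best_d[v] <- d; best_e[v] <- graph$edges$id[live[k]]
        best_arc[v] <- arcs[[k]][j]
      }
    }
  }
  # junction nodes joining a capillary branch to a precollector-like link
  deg_nodes <- graph$nodes
  cls <- graph$edges$class
  linkish <- cls %in% c("precollector_link", "cropped_precollector", "border_ambiguous")
  cap <- cls %in% "capillary_branch"
  has_cap <- has_link <- rep(FALSE, nrow(deg_nodes))
  for (j in which(cap)) has_cap[c(graph$edges$from[j], graph$edges$to[j])] <- TRUE
  for (j in which(linkish)) has_link[c(graph$edges$from[j], graph$edges$to[j])] <- TRUE
  jn <- which(has_cap & has_link)
  jn_pos <- as.matrix(deg_nodes[jn, c("z_um", "y_um", "x_um")])

  for (v in seq_len(nrow(valves))) {
    if (!is.finite(best_d[v]) || best_d[v] > 2 * junction_radius_um) {
      valves$position_class[v] <- "unassigned"
      next
    }
    valves$edge_id[v] <- best_e[v]
    valves$distance_to_edge_um[v] <- best_d[v]
    valves$arc_um[v] <- best_arc[v]
    e <- which(graph$edges$id == best_e[v])
    near_junction <- length(jn) > 0 &&
      min(sqrt(rowSums(sweep(jn_pos, 2, pts[v, ])^2))) <= junction_radius_um
    if (near_junction) {
      valves$position_class[v] <- "base_of_capillary"
    } else if (isTRUE(cap[e])) {
      valves$position_class[v] <- "within_capillary"
    } else {
      lay <- graph$edges$layer[e]
      valves$position_class[v] <- if (!is.na(lay) && lay == 3L) "collector" else "precollector"
    }
  }
  valves
}

#' Assign depth layers to valves or graph edges
#'
#' Layer 1 for `z < bands[1]`, layer 2 for `bands[1] <= z < bands[2]`,
#' layer 3 otherwise (half-open convention: a z exactly on a boundary goes
#' to the deeper band).  Edges use the median z of their path.
#'
#' @param x a valve data.frame (column `z_um`) or a `lymph_graph`.
#' @param z_bands_um strictly increasing depth boundaries (default
#'   `c(150, 210)`), um below the epidermal surface.
#' @return `x` with a `layer` column filled in (`edges$layer` for graphs).
#' @export
assign_layers <- function(x, z_bands_um = c(150, 210)) {
  if (is.unsorted(z_bands_um, strictly = TRUE)) stop("z bands must be sorted")
  if (inherits(x, "lymph_graph")) {
    if (nrow(x$edges)) {
      med_z <- vapply(x$paths, function(p) stats::median(p[, 1]), numeric(1))
      x$edges$layer <- as.integer(findInterval(med_z, z_bands_um) + 1L)
    }
    return(x)
  }
  if (nrow(x)) x$layer <- as.integer(findInterval(x$z_um, z_bands_um) + 1L)
  x
}

#' Export the valve table as CSV
#' @param valves valve data.frame.
#' @param path output path.
#' @param config_md5 optional provenance hash column.
#' @return `path`, invisibly.
#' @export
write_valves_csv <- function(valves, path, config_md5 = NA_character_) {
  valves$config_md5 <- config_md5
  write.csv(valves, path, row.names = FALSE)
  invisible(path)
}
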