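#' Parameters of the synthetic phantom generator
#'
#' The defaults describe the stated world the pipeline is tested against: a
#' dermal lymphatic network in a 540 um cube (300^3 voxels at 1.8 um) with
#' three depth layers -- blind-ended capillaries ascending obliquely toward
#' the epidermis (tips near 100-135 um, bodies centered near 140 um), a
#' branched precollector plexus (3 x 3 grid of tubes) at 170 um, and two
#' collector tubes at 240 um connected to the plexus -- plus bright compact
#' intraluminal valves, hair-follicle-like distractor blobs, a depth-ramped
#' background and additive Gaussian noise (optional Poisson).  Radii follow
#' dermal lymphatics (wide, thin-walled vessels) and are all above the 18 um
#' structuring radius so the top-hat suppresses vessels while keeping
#' valves.  See the methods vignette for the rationale of every default.
#'
#' @param ... named overrides of the defaults.
#' @return a named list of generator parameters.
#' @export
phantom_params <- function(...) {
  p <- list(
    box_um = c(540, 540, 540),
    plexus_z_um = 170,
    collector_z_um = 240,
    plexus_lines_um = c(91, 271, 451),
    n_capillaries = NULL,            # NULL: one per interior plexus span (12)
    n_collectors = 2,
    capillary_length_um = 115,
    capillary_length_sd_um = 12,
    capillary_length_range_um = c(95, 140),
    capillary_radius_um = 22,
    capillary_tilt_deg = 35,         # mean inclination from vertical
    capillary_azimuth_deg = 45,
    orientation_sd_deg = 15,         # von Mises-Fisher angular scatter
    precollector_radius_um = 20,
    collector_radius_um = 24,
    capillary_valve_base_arc_um = 15,
    capillary_valve_fracs = c(0.5, 0.85),
    precollector_valve_spacing_um = NULL,  # NULL: one valve per span (midpoint rule)
    collector_valve_spacing_um = 180,
    valve_semi_axes_um = c(9, 7, 7),       # along-axis, transverse, transverse
    valve_gain = 80,
    vessel_level = 100,
    background_level = 10,
    depth_gradient = 0.03,           # intensity per um depth
    n_distractors = 6,
    distractor_radius_um = 17,
    distractor_level = 150,
    noise_sigma = 12,
    poisson = FALSE
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown phantom parameter(s): ", paste(bad, collapse = ", "))
    p <- modifyList(p, over, keep.null = TRUE)
  }
  p
}

# one draw from a von Mises-Fisher distribution on the sphere
rvmf_one <- function(mu, kappa) {
  mu <- mu / sqrt(sum(mu^2))
  u <- runif(1)
  ct <- if (kappa < 1e-8) 2 * u - 1 else
    1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  st <- sqrt(max(0, 1 - ct^2))
  phi <- runif(1, 0, 2 * pi)
  # tangent basis at mu
  a <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- a - sum(a * mu) * mu; t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(mu[2] * t1[3] - mu[3] * t1[2],
          mu[3] * t1[1] - mu[1] * t1[3],
          mu[1] * t1[2] - mu[2] * t1[1])
  ct * mu + st * (cos(phi) * t1 + sin(phi) * t2)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  set.seed(seed)
  expr
}

#' Build a parametric phantom network specification
#'
#' Deterministic for fixed `(params, seed)`.  Capillaries are open-ended
#' (the tip connects to nothing); every capillary's deep end joins a
#' precollector node, subdividing the plexus span it sits on.  Valves are
#' placed on capillaries (one at the base, more along the body), on
#' precollector spans and on collectors; when an explicit spacing `s` is
#' given for a vessel type, valves sit at arc lengths `k * s` strictly
#' inside each edge.
#'
#' @param params list from [phantom_params()].
#' @param seed integer seed.
#' @return an object of class `phantom_spec`: node table, segment table
#'   (with per-segment radii and types), valve table, distractors,
#'   intensity/noise model and the seed.
#' @export
build_network_spec <- function(params = phantom_params(), seed = 1) {
  with_seed(seed, build_spec_impl(params, seed))
}

build_spec_impl <- function(p, seed) {
  box <- p$box_um
  nodes <- data.frame(id = integer(0), z = numeric(0), y = numeric(0), x = numeric(0))
  segs <- data.frame(id = integer(0), type = character(0), from = integer(0),
                     to = integer(0), radius_um = numeric(0))
  valves <- data.frame(id = integer(0), seg_id = integer(0), arc_um = numeric(0),
                       a_um = numeric(0), b_um = numeric(0), c_um = numeric(0),
                       gain = numeric(0))
  add_node <- function(z, y, x) {
    nodes[nrow(nodes) + 1L, ] <<- list(nrow(nodes) + 1L, z, y, x)
    nrow(nodes)
  }
  add_seg <- function(type, from, to, r) {
    segs[nrow(segs) + 1L, ] <<- list(nrow(segs) + 1L, type, from, to, r)
    nrow(segs)
  }
  add_valve <- function(seg_id, arc) {
    sa <- p$valve_semi_axes_um
    valves[nrow(valves) + 1L, ] <<- list(nrow(valves) + 1L, seg_id, arc,
                                         sa[1], sa[2], sa[3], p$valve_gain)
  }
  n_cap <- p$n_capillaries
  # the plexus exists to host capillary bases; it is generated when
  # capillaries are requested, or when precollector valves are explicitly
  # asked for (so `n_capillaries = 0, n_collectors = 0` is the empty world)
  want_plexus <- length(p$plexus_lines_um) > 0 &&
    ((is.null(n_cap) || n_cap > 0) || !is.null(p$precollector_valve_spacing_um))
  lines <- p$plexus_lines_um

  # ---- precollector plexus: grid of lines at plexus_z -------------------
  base_sites <- list()   # candidate capillary base sites on interior spans
  spans <- list()        # interior spans: (orient, line_pos, lo, hi)
  if (want_plexus) {
    if (any(lines <= 0 | lines >= box[2]) || length(lines) < 1)
      stop("plexus lines must lie inside the box")
    breaks <- c(0, lines, box[2])
    for (orient in c("x", "y")) {            # lines running along this axis
      for (lp in lines) {
        for (i in seq_len(length(breaks) - 1)) {
          lo <- breaks[i]; hi <- breaks[i + 1]
          if (lo %in% lines && hi %in% lines)  # interior intersection-to-intersection span
            spans[[length(spans) + 1L]] <-
              list(orient = orient, line = lp, lo = lo, hi = hi)
        }
      }
    }
    for (frac in c(0.5, 0.3, 0.7)) for (s in spans)
      base_sites[[length(base_sites) + 1L]] <-
        list(orient = s$orient, line = s$line, pos = s$lo + frac * (s$hi - s$lo))
  }
  if (is.null(n_cap)) n_cap <- length(spans)
  if (n_cap > length(base_sites))
    stop("box too small for requested counts: only ", length(base_sites),
         " capillary base sites available")

  # plexus nodes: split every line at intersections and capillary bases
  site_use <- if (n_cap > 0) base_sites[seq_len(n_cap)] else list()
  plexus_node <- function(orient, along, line_pos) {
    if (orient == "x") add_node(p$plexus_z_um, line_pos, along)
    else add_node(p$plexus_z_um, along, line_pos)
  }
  node_lookup <- new.env()
  get_plexus_node <- function(orient, along, line_pos) {
    key <- sprintf("%s_%.6f_%.6f", if (orient == "x") "y" else "x", line_pos, along)
    # intersections are shared between the two orientations
    is_cross <- any(abs(along - lines) < 1e-9)
    if (is_cross) key <- sprintf("cross_%.6f_%.6f",
                                 if (orient == "x") line_pos else along,
                                 if (orient == "x") along else line_pos)
    if (!is.null(node_lookup[[key]])) return(node_lookup[[key]])
    id <- plexus_node(orient, along, line_pos)
    node_lookup[[key]] <- id
    id
  }
  if (want_plexus) {
    for (orient in c("x", "y")) for (lp in lines) {
      cuts <- sort(unique(c(0, box[if (orient == "x") 3 else 2], lines,
                            vapply(site_use, function(s)
                              if (s$orient == orient && abs(s$line - lp) < 1e-9)
                                s$pos else NA_real_, numeric(1)))))
      cuts <- cuts[!is.na(cuts)]
      ids <- vapply(cuts, function(a) get_plexus_node(orient, a, lp), integer(1))
      for (i in seq_len(length(ids) - 1))
        add_seg("precollector", ids[i], ids[i + 1], p$precollector_radius_um)
    }
  }

  # ---- capillaries ------------------------------------------------------
  tilt <- p$capillary_tilt_deg * pi / 180
  az <- p$capillary_azimuth_deg * pi / 180
  mu <- c(-cos(tilt), sin(tilt) * sin(az), sin(tilt) * cos(az))  # (z,y,x), up
  kappa <- if (p$orientation_sd_deg <= 0) Inf else
    (180 / (pi * p$orientation_sd_deg))^2
  margin <- p$capillary_radius_um + 2
  for (s in site_use) {
    base_id <- get_plexus_node(s$orient, s$pos, s$line)
    bp <- as.numeric(nodes[base_id, c("z", "y", "x")])
    ok <- FALSE
    for (try in 1:100) {
      d <- if (is.finite(kappa)) rvmf_one(mu, kappa) else mu
      if (d[1] > -0.2) next                   # must ascend toward the surface
      L <- min(max(rnorm(1, p$capillary_length_um, p$capillary_length_sd_um),
                   p$capillary_length_range_um[1]), p$capillary_length_range_um[2])
      tip <- bp + L * d
      if (all(tip >= margin) && all(tip <= box - margin)) { ok <- TRUE; break }
    }
    if (!ok) stop("box too small for requested counts: capillary does not fit")
    tip_id <- add_node(tip[1], tip[2], tip[3])
    sid <- add_seg("capillary", base_id, tip_id, p$capillary_radius_um)
    if (!is.null(p$capillary_valve_base_arc_um) &&
        p$capillary_valve_base_arc_um < L)
      add_valve(sid, p$capillary_valve_base_arc_um)
    for (f in p$capillary_valve_fracs) add_valve(sid, f * L)
  }

  # ---- collectors and connectors ---------------------------------------
  if (p$n_collectors > 0) {
    if (!want_plexus) {
      # stand-alone collectors across the box, no connectors
      xs <- seq(box[3] / (p$n_collectors + 1), by = box[3] / (p$n_collectors + 1),
                length.out = p$n_collectors)
      for (x0 in xs) {
        a <- add_node(p$collector_z_um, 0, x0)
        b <- add_node(p$collector_z_um, box[2], x0)
        add_seg("collector", a, b, p$collector_radius_um)
      }
    } else {
      if (p$n_collectors > length(lines))
        stop("box too small for requested counts: collectors exceed plexus lines")
      xs <- lines[order(abs(lines - box[3] / 2), decreasing = TRUE)][seq_len(p$n_collectors)]
      y_mid <- lines[ceiling(length(lines) / 2)]
      for (x0 in xs) {
        top <- get_plexus_node("y", y_mid, x0)   # plexus intersection above
        drop_id <- add_node(p$collector_z_um, y_mid, x0)
        add_seg("connector", top, drop_id, p$precollector_radius_um)
        a <- add_node(p$collector_z_um, 0, x0)
        b <- add_node(p$collector_z_um, box[2], x0)
        add_seg("collector", a, drop_id, p$collector_radius_um)
        add_seg("collector", drop_id, b, p$collector_radius_um)
      }
    }
  }

  # ---- valves on precollectors and collectors --------------------------
  seg_len <- function(i) {
    a <- as.numeric(nodes[segs$from[i], c("z", "y", "x")])
    b <- as.numeric(nodes[segs$to[i], c("z", "y", "x")])
    sqrt(sum((b - a)^2))
  }
  if (!is.null(p$precollector_valve_spacing_um)) {
    s <- p$precollector_valve_spacing_um
    for (i in which(segs$type == "precollector")) {
      L <- seg_len(i)
      for (k in seq_len(max(0, ceiling(L / s) - 1)))
        if (k * s < L - 1e-9) add_valve(i, k * s)
    }
  } else if (want_plexus) {
    # default rule: one valve per interior span, at the midpoint of the
    # sub-edge leaving the span's first intersection
    for (s in spans) {
      # find the plexus segment starting at the span's lower intersection
      from_id <- get_plexus_node(s$orient, s$lo, s$line)
      cand <- which(segs$type == "precollector" & segs$from == from_id)
      # pick the one heading into this span (positive along direction)
      for (i in cand) {
        b <- as.numeric(nodes[segs$to[i], c("z", "y", "x")])
        a <- as.numeric(nodes[segs$from[i], c("z", "y", "x")])
        along <- if (s$orient == "x") 3 else 2
        line_ax <- if (s$orient == "x") 2 else 3
        if (abs(a[line_ax] - s$line) < 1e-9 && abs(b[line_ax] - s$line) < 1e-9 &&
            b[along] > a[along] && a[along] >= s$lo - 1e-9 && b[along] <= s$hi + 1e-9) {
          L <- seg_len(i)
          if (L >= 50) add_valve(i, L / 2)
          break
        }
      }
    }
  }
  if (!is.null(p$collector_valve_spacing_um)) {
    col_ids <- which(segs$type == "collector")
    # spacing is measured along each full collector line; convert to arcs on
    # the (possibly split) collector segments, grouped by x position
    xs <- vapply(col_ids, function(i) nodes$x[segs$from[i]], numeric(1))
    for (x0 in unique(xs)) {
      ids <- col_ids[abs(xs - x0) < 1e-9]
      # order segments along y
      y0 <- vapply(ids, function(i) min(nodes$y[c(segs$from[i], segs$to[i])]), numeric(1))
      ids <- ids[order(y0)]
      offs <- 0
      total <- sum(vapply(ids, seg_len, numeric(1)))
      marks <- seq(p$collector_valve_spacing_um, total - 1e-9,
                   by = p$collector_valve_spacing_um)
      marks <- marks[marks < total - 1e-9]
      for (i in ids) {
        L <- seg_len(i)
        loc <- marks[marks > offs + 1e-9 & marks < offs + L - 1e-9] - offs
        # arc measured from the segment's lower-y node; reorient if needed
        a_y <- nodes$y[segs$from[i]]; b_y <- nodes$y[segs$to[i]]
        for (m in loc) add_valve(i, if (a_y <= b_y) m else L - m)
        offs <- offs + L
      }
    }
  }

  # ---- distractors ------------------------------------------------------
  distract <- data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                         radius_um = numeric(0), level = numeric(0))
  if (p$n_distractors > 0) {
    seg_pts <- lapply(seq_len(nrow(segs)), function(i) {
      a <- as.numeric(nodes[segs$from[i], c("z", "y", "x")])
      b <- as.numeric(nodes[segs$to[i], c("z", "y", "x")])
      list(a = a, b = b, r = segs$radius_um[i])
    })
    min_clear <- 60
    for (k in seq_len(p$n_distractors)) {
      for (try in 1:200) {
        pos <- runif(3) * (box - 2 * p$distractor_radius_um) + p$distractor_radius_um
        d_ok <- TRUE
        for (sp in seg_pts) {
          ab <- sp$b - sp$a
          t <- sum((pos - sp$a) * ab) / sum(ab^2)
          t <- min(max(t, 0), 1)
          if (sqrt(sum((pos - (sp$a + t * ab))^2)) < sp$r + min_clear) {
            d_ok <- FALSE; break
          }
        }
        if (d_ok) {
          distract[nrow(distract) + 1L, ] <- list(pos[1], pos[2], pos[3],
                                                  p$distractor_radius_um,
                                                  p$distractor_level)
          break
        }
      }
    }
  }

  spec <- structure(list(
    box_um = box, nodes = nodes, segments = segs, valves = valves,
    distractors = distract,
    intensities = list(vessel = p$vessel_level,
                       background = p$background_level,
                       depth_gradient = p$depth_gradient,
                       valve_gain = p$valve_gain),
    noise = list(sigma = p$noise_sigma, poisson = isTRUE(p$poisson)),
    seed = seed, params = p), class = "phantom_spec")
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  n <- spec$nodes
  if (nrow(n)) {
    pts <- as.matrix(n[, c("z", "y", "x")])
    if (any(pts < -1e-6) || any(sweep(pts, 2, spec$box_um) > 1e-6))
      stop("phantom centerlines fall outside the box")
  }
  if (any(spec$segments$radius_um <= 0)) stop("radii must be > 0")
  for (i in seq_len(nrow(spec$valves))) {
    v <- spec$valves[i, ]
    L <- seg_length(spec, v$seg_id)
    if (v$arc_um < 0 || v$arc_um > L)
      stop("valve arc-length outside its edge")
  }
  invisible(spec)
}

seg_length <- function(spec, i) {
  a <- as.numeric(spec$nodes[spec$segments$from[i], c("z", "y", "x")])
  b <- as.numeric(spec$nodes[spec$segments$to[i], c("z", "y", "x")])
  sqrt(sum((b - a)^2))
}

seg_endpoints <- function(spec, i) {
  list(a = as.numeric(spec$nodes[spec$segments$from[i], c("z", "y", "x")]),
       b = as.numeric(spec$nodes[spec$segments$to[i], c("z", "y", "x")]))
}

#' @export
#' @method print phantom_spec
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> box %s um, %d nodes, %d segments (%s), %d valves, %d distractors\n",
              paste(x$box_um, collapse = "x"), nrow(x$nodes), nrow(x$segments),
              paste(names(table(x$segments$type)), table(x$segments$type),
                    collapse = ", "),
              nrow(x$valves), nrow(x$distractors)))
  invisible(x)
}

#' Ground-truth network graph of a phantom spec
#'
#' The analytic graph: segments become edges with finely sampled straight
#' polyline paths; classification, border rules and layer assignment use
#' the same functions as the measured pipeline.
#'
#' @param spec a `phantom_spec`.
#' @param step_um path sampling step.
#' @param z_bands_um layer boundaries for [assign_layers()].
#' @return a classified, layer-assigned `lymph_graph`.
#' @export
true_graph <- function(spec, step_um = 1.5, z_bands_um = c(150, 210)) {
  if (!nrow(spec$segments))
    return(empty_graph(NA, c(0, 0, 0), NA))
  pos <- as.matrix(spec$nodes[, c("z", "y", "x")])
  paths <- lapply(seq_len(nrow(spec$segments)), function(i) {
    ep <- seg_endpoints(spec, i)
    L <- sqrt(sum((ep$b - ep$a)^2))
    nstep <- max(2L, as.integer(ceiling(L / step_um)) + 1L)
    t <- seq(0, 1, length.out = nstep)
    cbind(ep$a[1] + t * (ep$b[1] - ep$a[1]),
          ep$a[2] + t * (ep$b[2] - ep$a[2]),
          ep$a[3] + t * (ep$b[3] - ep$a[3]))
  })
  edges <- data.frame(id = spec$segments$id, from = spec$segments$from,
                      to = spec$segments$to,
                      length_um = vapply(seq_len(nrow(spec$segments)),
                                         function(i) seg_length(spec, i), numeric(1)),
                      class = NA_character_, layer = NA_integer_, border = NA)
  g <- new_lymph_graph(pos, edges, paths, NULL, NA, c(0, 0, 0), NA,
                       rbind(c(0, 0, 0), spec$box_um))
  g <- classify_edges(g)
  g <- apply_border_rules(g)
  assign_layers(g, z_bands_um)
}

#' Ground-truth valve table of a phantom spec
#'
#' Valve-like records computed from the spec: analytic centroids (node
#' position + arc along the segment direction), exact ellipsoid volumes
#' `4/3 pi a b c`, the segment (edge) id and arc length.
#'
#' @param spec a `phantom_spec`.
#' @return a valve data.frame in the same layout as [detect_valve_blobs()].
#' @export
true_valves <- function(spec) {
  out <- valve_table(nrow(spec$valves))
  if (!nrow(spec$valves)) return(out)
  for (i in seq_len(nrow(spec$valves))) {
    v <- spec$valves[i, ]
    ep <- seg_endpoints(spec, v$seg_id)
    u <- (ep$b - ep$a) / sqrt(sum((ep$b - ep$a)^2))
    c0 <- ep$a + v$arc_um * u
    out$z_um[i] <- c0[1]; out$y_um[i] <- c0[2]; out$x_um[i] <- c0[3]
    out$volume_um3[i] <- 4 / 3 * pi * v$a_um * v$b_um * v$c_um
    out$edge_id[i] <- v$seg_id
    out$arc_um[i] <- v$arc_um
  }
  out
}

#' Analytic morphometrics of a phantom spec
#'
#' The oracle for the morphometrics module, computed from the parametric
#' description (never from the raster).  Length density is the summed
#' centerline length over the box volume; volume density sums capsule
#' volumes with documented first-order overlap corrections (free-end
#' hemispheres added; attachment stubs and grid-crossing lens volumes
#' subtracted); valve density, per-layer counts, capillary statistics,
#' orientations and inter-valve distances are enumerated from the spec
#' lists.
#'
#' @param spec a `phantom_spec`.
#' @param box_um sample volume bounds; defaults to the spec's box.
#' @param junction_radius_um,z_bands_um classification parameters (pipeline
#'   defaults).
#' @return a `lymph_metrics` object.
#' @export
analytic_metrics <- function(spec, box_um = NULL, junction_radius_um = 20,
                             z_bands_um = c(150, 210)) {
  if (is.null(box_um)) box_um <- spec$box_um
  vol <- prod(box_um)
  if (!is.finite(vol) || vol <= 0) stop("zero box volume")
  g <- true_graph(spec, z_bands_um = z_bands_um)
  tv <- true_valves(spec)
  if (nrow(tv)) {
    tv <- classify_valve_positions(tv, g, junction_radius_um)
    tv <- assign_layers(tv, z_bands_um)
  }
  keep <- retained_edges(g)
  tot_len <- sum(g$edges$length_um[keep])
  cap_len <- sum(g$edges$length_um[g$edges$class %in% "capillary_branch"])
  caps <- capillary_stats(g)
  ori <- if (nrow(caps)) t(vapply(g$paths[match(caps$edge_id, g$edges$id)],
                                  capillary_orientation, numeric(3)))
    else matrix(numeric(0), 0, 3,
                dimnames = list(NULL, c("roll_deg", "pitch_deg", "yaw_deg")))
  assigned <- tv$position_class != "unassigned"
  pos_frac <- if (any(assigned)) {
    tb <- table(tv$position_class[assigned]); as.list(tb / sum(tb))
  } else list()
  structure(list(
    sample_volume_um3 = vol,
    volume_density = analytic_vessel_volume(spec) / vol,
    length_density_mm_per_mm3 = 1e6 * tot_len / vol,
    capillary_length_fraction = if (tot_len > 0) cap_len / tot_len else 0,
    capillary_lengths_um = caps$length_um,
    capillary_z_range_um = caps[, c("edge_id", "z_min_um", "z_max_um")],
    orientations_deg = ori,
    n_valves = nrow(tv),
    valve_density_per_mm3 = nrow(tv) / (vol / 1e9),
    valves_per_layer = valves_per_layer(tv, g, vol),
    intervalve_distances_um = intervalve_distances(tv, g),
    valve_position_fractions = pos_frac,
    intensity_by_valve_position = NULL,
    true_valve_table = tv,
    true_graph = g
  ), class = "lymph_metrics")
}

# capsule union volume with first-order overlap corrections
analytic_vessel_volume <- function(spec) {
  if (!nrow(spec$segments)) return(0)
  v <- 0
  deg <- tabulate(c(spec$segments$from, spec$segments$to), nbins = nrow(spec$nodes))
  for (i in seq_len(nrow(spec$segments)))
    v <- v + pi * spec$segments$radius_um[i]^2 * seg_length(spec, i)
  # free ends get a hemispherical cap, except ends cut by the box border
  # (their caps are clipped away in any raster)
  for (nd in which(deg == 1)) {
    r <- spec$segments$radius_um[spec$segments$from == nd | spec$segments$to == nd][1]
    pos <- as.numeric(spec$nodes[nd, c("z", "y", "x")])
    at_border <- any(pos < r) || any(spec$box_um - pos < r)
    if (!at_border) v <- v + 2 / 3 * pi * r^3
  }
  # attachment stubs: a segment ending on a node interior to a host tube of
  # radius R double-counts roughly a cylinder stub pi r^2 R
  for (nd in which(deg >= 3)) {
    inc <- which(spec$segments$from == nd | spec$segments$to == nd)
    rr <- spec$segments$radius_um[inc]
    if (length(inc) == 4 && length(unique(round(rr, 6))) == 1) {
      # grid crossing of two equal through-tubes: Steinmetz intersection
      v <- v - 16 / 3 * rr[1]^3
    } else {
      # T-junction: the radius occurring most often is the through tube
      # (host); attachments double-count roughly a stub pi r^2 R inside it
      tb <- table(round(rr, 6))
      host <- as.numeric(names(tb)[which.max(tb)])
      att <- rr[round(rr, 6) != round(host, 6)]
      if (!length(att) && length(rr) > 2) att <- rr[-(1:2)]
      for (r in att) v <- v - pi * r^2 * host
    }
  }
  v
}
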