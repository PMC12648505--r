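#' Rasterize a phantom spec into a volume with ground truth
#'
#' Vessels are rendered as capsules (cylinders with spherical caps) around
#' their centerlines at the vessel intensity; valves as brighter ellipsoids
#' aligned with the local vessel axis; distractors as spheres outside the
#' network; a depth-dependent linear background ramp underlies everything.
#' Noise (additive Gaussian, optional Poisson) is applied after labeling,
#' so `label_volume` is noise-free.  Rendering is bit-identical for a fixed
#' `(spec, spacing)`.
#'
#' @param spec a `phantom_spec`.
#' @param spacing_um voxel spacing (scalar or z,y,x triple), um.
#' @param keep_type_volume also return a per-voxel vessel-type array
#'   (1 capillary, 2 precollector/connector, 3 collector); off by default
#'   to save memory.
#' @return list with `volume` (a `lymph_volume`) and `truth`: `label_volume`
#'   (0 background, 1 vessel, 2 valve, 3 distractor), `true_graph`,
#'   `true_valves` (with rasterized voxel counts) and `analytic`
#'   ([analytic_metrics()] of the spec).
#' @export
render_volume <- function(spec, spacing_um = c(1.8, 1.8, 1.8),
                          keep_type_volume = FALSE) {
  if (length(spacing_um) == 1) spacing_um <- rep(spacing_um, 3)
  if (any(!is.finite(spacing_um)) || any(spacing_um <= 0))
    stop("spacing must be positive and finite")
  pars <- c(spec$box_um, unlist(spec$intensities), spec$noise$sigma)
  if (any(!is.finite(pars))) stop("non-finite phantom parameters")
  radii <- spec$segments$radius_um
  if (length(radii)) {
    if (max(spacing_um) > min(radii))
      warning("spacing coarser than the smallest vessel radius; rendering anyway")
    else if (min(radii) < 4 * max(spacing_um))
      warning("fewer than ~8 voxels across the smallest radius feature")
  }
  dims <- pmax(1L, as.integer(round_half_away(spec$box_um / spacing_um)))
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  zc <- ((seq_len(nz)) - 0.5) * spacing_um[1]
  yc <- ((seq_len(ny)) - 0.5) * spacing_um[2]
  xc <- ((seq_len(nx)) - 0.5) * spacing_um[3]

  vol <- array(spec$intensities$background +
                 spec$intensities$depth_gradient * zc, dims)
  lab <- array(0L, dims)
  typ <- if (keep_type_volume) array(0L, dims) else NULL

  sub_idx <- function(lo, hi) {
    i0 <- pmax(1L, as.integer(floor(lo / spacing_um)) + 1L)
    i1 <- pmin(dims, as.integer(ceiling(hi / spacing_um)))
    list(i0 = i0, i1 = i1)
  }
  sub_arrays <- function(i0, i1) {
    ns <- i1 - i0 + 1L
    Z <- array(zc[i0[1]:i1[1]], ns)
    Y <- array(rep(yc[i0[2]:i1[2]], each = ns[1]), ns)
    X <- array(rep(xc[i0[3]:i1[3]], each = ns[1] * ns[2]), ns)
    G <- array((i0[1]:i1[1]) - 1L, ns) +
      array(rep(((i0[2]:i1[2]) - 1L) * nz, each = ns[1]), ns) +
      array(rep(((i0[3]:i1[3]) - 1L) * nz * ny, each = ns[1] * ns[2]), ns) + 1L
    list(Z = Z, Y = Y, X = X, G = G)
  }

  type_code <- c(capillary = 1L, precollector = 2L, connector = 2L,
                 collector = 3L)
  for (i in seq_len(nrow(spec$segments))) {
    ep <- seg_endpoints(spec, i)
    r <- spec$segments$radius_um[i]
    si <- sub_idx(pmin(ep$a, ep$b) - r - max(spacing_um),
                  pmax(ep$a, ep$b) + r + max(spacing_um))
    if (any(si$i1 < si$i0)) next
    sa <- sub_arrays(si$i0, si$i1)
    ab <- ep$b - ep$a
    L2 <- sum(ab^2)
    if (L2 == 0) next
    t <- ((sa$Z - ep$a[1]) * ab[1] + (sa$Y - ep$a[2]) * ab[2] +
            (sa$X - ep$a[3]) * ab[3]) / L2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (sa$Z - ep$a[1] - t * ab[1])^2 + (sa$Y - ep$a[2] - t * ab[2])^2 +
      (sa$X - ep$a[3] - t * ab[3])^2
    sel <- sa$G[d2 <= r^2]
    vol[sel] <- spec$intensities$vessel
    lab[sel] <- 1L
    if (keep_type_volume) typ[sel] <- type_code[[spec$segments$type[i]]]
  }

  valve_counts <- integer(nrow(spec$valves))
  for (i in seq_len(nrow(spec$valves))) {
    v <- spec$valves[i, ]
    ep <- seg_endpoints(spec, v$seg_id)
    u <- (ep$b - ep$a) / sqrt(sum((ep$b - ep$a)^2))
    c0 <- ep$a + v$arc_um * u
    ext <- max(v$a_um, v$b_um, v$c_um)
    si <- sub_idx(c0 - ext - max(spacing_um), c0 + ext + max(spacing_um))
    if (any(si$i1 < si$i0)) next
    sa <- sub_arrays(si$i0, si$i1)
    dz <- sa$Z - c0[1]; dy <- sa$Y - c0[2]; dx <- sa$X - c0[3]
    t <- dz * u[1] + dy * u[2] + dx * u[3]
    rho2 <- dz^2 + dy^2 + dx^2 - t^2
    sel <- sa$G[(t / v$a_um)^2 + rho2 / (v$b_um^2) <= 1]
    vol[sel] <- spec$intensities$vessel + v$gain
    lab[sel] <- 2L
    valve_counts[i] <- length(sel)
  }

  for (i in seq_len(nrow(spec$distractors))) {
    d <- spec$distractors[i, ]
    c0 <- c(d$z, d$y, d$x)
    si <- sub_idx(c0 - d$radius_um - max(spacing_um),
                  c0 + d$radius_um + max(spacing_um))
    if (any(si$i1 < si$i0)) next
    sa <- sub_arrays(si$i0, si$i1)
    d2 <- (sa$Z - c0[1])^2 + (sa$Y - c0[2])^2 + (sa$X - c0[3])^2
    sel <- sa$G[d2 <= d$radius_um^2]
    sel <- sel[lab[sel] == 0L]
    vol[sel] <- d$level
    lab[sel] <- 3L
  }

  if (spec$noise$poisson || spec$noise$sigma > 0) {
    vol <- with_seed(spec$seed * 1000L + 7L, {
      v <- vol
      if (spec$noise$poisson) v[] <- rpois(length(v), pmax(v, 0))
      if (spec$noise$sigma > 0)
        v <- v + rnorm(length(v), 0, spec$noise$sigma)
      pmax(v, 0)
    })
  }

  tvs <- true_valves(spec)
  if (nrow(tvs)) tvs$voxel_count <- valve_counts
  out <- list(
    volume = volume3d(vol, spacing_um, c(0, 0, 0), "lymphatic"),
    truth = list(
      label_volume = volume3d(lab + 0, spacing_um, c(0, 0, 0), "labels"),
      true_graph = true_graph(spec),
      true_valves = tvs,
      analytic = analytic_metrics(spec)))
  if (keep_type_volume)
    out$truth$type_volume <- volume3d(typ + 0, spacing_um, c(0, 0, 0), "types")
  out
}
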