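# small analytic graph builders used across the morphometric tests
straight_graph <- function(p0, p1, n = 60, class = "capillary_branch") {
  path <- cbind(seq(p0[1], p1[1], length.out = n),
                seq(p0[2], p1[2], length.out = n),
                seq(p0[3], p1[3], length.out = n))
  g <- lymphnet3d:::new_lymph_graph(
    rbind(p0, p1),
    data.frame(id = 1L, from = 1L, to = 2L,
               length_um = sqrt(sum((p1 - p0)^2)), class = class,
               layer = NA_integer_, border = FALSE),
    list(path), NULL, NA, c(0, 0, 0), NA, rbind(c(0, 0, 0), c(1e3, 1e3, 1e3)))
  g
}

test_that("network density of an empty mask is zero", {
  m <- seg_mask(array(FALSE, c(10, 10, 10)), 1.8)
  d <- network_density(m, lymphnet3d:::empty_graph(), prod(extent_um(m)))
  expect_equal(d$volume_density, 0)
  expect_equal(d$length_density_mm_per_mm3, 0)
  expect_error(network_density(m, lymphnet3d:::empty_graph(), 0), "> 0")
})

test_that("density of a rendered tube matches closed forms within 5%", {
  # collectors run along y: a 1000 um tube of radius 12 (the stated example
  # scale; blunt-end skeleton recession is absolute, ~1 voxel radius per end)
  p <- phantom_params(box_um = c(80, 1000, 80), plexus_lines_um = numeric(0),
                      n_capillaries = 0, n_collectors = 1, n_distractors = 0,
                      collector_z_um = 40, collector_radius_um = 12,
                      collector_valve_spacing_um = NULL, noise_sigma = 0,
                      background_level = 0, depth_gradient = 0)
  spec <- build_network_spec(p, seed = 1)
  r <- render_volume(spec, 1.8)
  mask <- seg_mask(r$truth$label_volume$data > 0, 1.8)
  g <- classify_edges(skeleton_to_graph(skeletonize(mask), 10))
  d <- network_density(mask, g, prod(spec$box_um))
  vol_true <- pi * 12^2 * 1000 / prod(spec$box_um)
  len_true <- 1e6 * 1000 / prod(spec$box_um)
  expect_lt(abs(d$volume_density - vol_true) / vol_true, 0.05)
  expect_lt(abs(d$length_density_mm_per_mm3 - len_true) / len_true, 0.05)
  # exact conservation: density times sample volume is the summed length
  keep <- lymphnet3d:::retained_edges(g)
  expect_equal(d$length_density_um_per_um3 * prod(spec$box_um),
               sum(g$edges$length_um[keep]))
})

test_that("capillary stats report one record per branch with z range", {
  g <- straight_graph(c(40, 100, 100), c(140, 100, 100))  # vertical, 100 um
  st <- capillary_stats(g)
  expect_equal(nrow(st), 1)
  expect_equal(st$length_um, 100)
  expect_equal(st$z_min_um, 40)
  expect_equal(st$z_max_um, 140)
  # a graph with only links yields an empty table
  g2 <- straight_graph(c(0, 0, 0), c(0, 0, 50), class = "precollector_link")
  expect_equal(nrow(capillary_stats(g2)), 0)
})

test_that("the Y phantom yields three capillary records", {
  g <- classify_edges(skeleton_to_graph(skeletonize(phantom_y_mask()), 10))
  expect_equal(nrow(capillary_stats(g)), 3)
})

test_that("orientation angles match the stated axis conventions", {
  along_z <- cbind(seq(0, 100, 2), 0, 0)
  expect_equal(unname(capillary_orientation(along_z)), c(0, 0, 0))
  along_x <- cbind(0, 0, seq(0, 100, 2))
  expect_equal(unname(capillary_orientation(along_x)), c(0, 90, 0))
  diag_xz <- cbind(seq(0, 70, 1), 0, seq(0, 70, 1))
  expect_equal(unname(capillary_orientation(diag_xz))[2], 45, tolerance = 0.05)
  expect_error(capillary_orientation(matrix(1, 1, 3)), "2 points")
})

test_that("orientation agrees with a direct eigen decomposition", {
  set.seed(30)
  d <- c(-0.6, 0.5, 0.62); d <- d / sqrt(sum(d^2))
  path <- t(sapply(seq(0, 120, 2), function(t) t * d)) +
    matrix(rnorm(183, 0, 0.3), ncol = 3)
  ang <- capillary_orientation(path)
  v <- if (d[1] < 0) -d else d
  expect_equal(ang[["pitch_deg"]], atan2(v[3], v[1]) * 180 / pi, tolerance = 0.5)
  expect_equal(ang[["roll_deg"]], atan2(v[2], v[1]) * 180 / pi, tolerance = 0.5)
})

test_that("multipoint length and range reproduce the hand-computed cases", {
  out <- multipoint_length(rbind(c(0, 0, 0), c(0, 4, 3), c(12, 4, 3)), c(1, 1, 1))
  expect_equal(unname(out), c(17, 13))
  out <- multipoint_length(rbind(c(0, 0, 0), c(5, 0, 0)), c(6.52, 1.2, 1.2))
  expect_equal(unname(out), c(32.6, 32.6))
  expect_equal(unname(multipoint_length(rbind(c(3, 3, 3)))), c(0, 0))
  expect_error(multipoint_length(matrix(numeric(0), 0, 3)), "empty")
})

test_that("valves_per_layer counts, lengths and rates are consistent", {
  spec <- build_network_spec(small_phantom_params(), seed = 1)
  g <- assign_layers(true_graph(spec), c(120, 190))
  tv <- true_valves(spec)
  tv <- classify_valve_positions(tv, g, 20)
  tv <- assign_layers(tv, c(120, 190))
  vol <- prod(spec$box_um)
  vpl <- valves_per_layer(tv, g, vol)
  # totals consistent with the global count of assigned valves
  expect_equal(sum(vpl$n_valves), sum(tv$position_class != "unassigned"))
  # counts match direct enumeration from the spec's z positions
  expect_equal(vpl$n_valves,
               vapply(1:3, function(l) sum(findInterval(tv$z_um, c(120, 190)) + 1 == l &
                                             tv$position_class != "unassigned"),
                      integer(1)))
  expect_equal(vpl$valves_per_mm3, vpl$n_valves / (vol / 1e9))
  # no valves: all zeros
  vpl0 <- valves_per_layer(lymphnet3d:::valve_table(0), g, vol)
  expect_true(all(vpl0$n_valves == 0))
})

test_that("inter-valve distances are consecutive arc differences per edge", {
  g <- straight_graph(c(0, 0, 0), c(0, 0, 200))
  tv <- lymphnet3d:::valve_table(3)
  tv$edge_id <- c(1L, 1L, 2L)
  tv$arc_um <- c(30, 90, 50)
  expect_equal(intervalve_distances(tv, g), 60)   # edge 2 has one valve only
  expect_equal(length(intervalve_distances(lymphnet3d:::valve_table(0), g)), 0)
})

test_that("channel-2 means split by valve side of the junction", {
  spec <- build_network_spec(small_phantom_params(n_distractors = 0), seed = 1)
  g <- true_graph(spec, z_bands_um = c(120, 190))
  r <- render_volume(spec, 2.4, keep_type_volume = TRUE)
  mask <- seg_mask(r$truth$label_volume$data > 0, 2.4)
  tv <- classify_valve_positions(true_valves(spec), g, 20)
  base <- tv[tv$position_class == "base_of_capillary", , drop = FALSE]
  expect_gt(nrow(base), 0)

  # uniform channel 2: upstream equals downstream
  ch_flat <- volume3d(array(42, dim(mask$data)), 2.4)
  out <- intensity_by_valve_position(ch_flat, mask, g, tv)
  expect_true(all(abs(out$upstream_mean - out$downstream_mean) < 1e-9))

  # channel 2 = 100 within the capillary tubes (nearest-axis), 10 elsewhere
  ch <- array(10, dim(mask$data))
  caps <- which(spec$segments$type == "capillary")
  ctr <- lymphnet3d:::vox_um(as.matrix(expand.grid(seq_len(dim(ch)[1]),
                                                   seq_len(dim(ch)[2]),
                                                   seq_len(dim(ch)[3]))),
                             rep(2.4, 3), c(0, 0, 0))
  seg_d <- function(i) {
    ep <- lymphnet3d:::seg_endpoints(spec, i)
    ab <- ep$b - ep$a
    t <- pmin(pmax(((ctr[, 1] - ep$a[1]) * ab[1] + (ctr[, 2] - ep$a[2]) * ab[2] +
                      (ctr[, 3] - ep$a[3]) * ab[3]) / sum(ab^2), 0), 1)
    sqrt((ctr[, 1] - ep$a[1] - t * ab[1])^2 + (ctr[, 2] - ep$a[2] - t * ab[2])^2 +
           (ctr[, 3] - ep$a[3] - t * ab[3])^2)
  }
  d_cap <- do.call(pmin, lapply(caps, seg_d))
  d_oth <- do.call(pmin, lapply(setdiff(seq_len(nrow(spec$segments)), caps), seg_d))
  ch[d_cap < d_oth] <- 100
  out <- intensity_by_valve_position(volume3d(array(ch, dim(mask$data)), 2.4),
                                     mask, g, tv)
  expect_true(all(abs(out$upstream_mean - 100) / 100 < 0.05))
  expect_true(all(abs(out$downstream_mean - 10) / 10 < 0.5))
  expect_true(all(out$downstream_mean < 30))
  # non-base valves are excluded
  expect_equal(nrow(out), nrow(base))
  # missing channel: warning and empty result
  expect_warning(res0 <- intensity_by_valve_position(NULL, mask, g, tv), "missing")
  expect_equal(nrow(res0), 0)
})

test_that("rotating the volume 90 degrees leaves densities unchanged", {
  spec <- build_network_spec(small_phantom_params(n_distractors = 0,
                                                  noise_sigma = 0), seed = 2)
  r <- render_volume(spec, 2.4)
  run <- function(vol) {
    m <- hysteresis_segment(vol, 50, 50)
    g <- classify_edges(skeleton_to_graph(skeletonize(m), 10))
    network_density(m, g, prod(extent_um(m)))
  }
  d1 <- run(r$volume)
  rot <- aperm(r$volume$data, c(1, 3, 2))
  rot <- rot[, , rev(seq_len(dim(rot)[3])), drop = FALSE]
  d2 <- run(volume3d(rot, 2.4))
  expect_equal(d1$volume_density, d2$volume_density, tolerance = 1e-12)
  expect_equal(d1$length_density_mm_per_mm3, d2$length_density_mm_per_mm3,
               tolerance = 0.02)
})

test_that("roll and yaw permute consistently under a 90-degree z rotation", {
  d <- c(-0.5, 0.3, 0.81)
  path <- t(sapply(seq(0, 100, 2), function(t) t * d))
  # rotation about z: (z, y, x) -> (z, x, -y)
  path_rot <- cbind(path[, 1], path[, 3], -path[, 2])
  a1 <- capillary_orientation(path)
  a2 <- capillary_orientation(path_rot)
  expect_equal(a2[["roll_deg"]], a1[["pitch_deg"]], tolerance = 1e-6)
  expect_equal(a2[["pitch_deg"]], -a1[["roll_deg"]], tolerance = 1e-6)
})
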