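make_full_mask <- function(dims, spacing = 1.8)
  seg_mask(array(TRUE, dims), spacing)

test_that("top-hat of a constant in-mask image is exactly zero", {
  v <- volume3d(array(50, c(40, 40, 40)), 1.8)
  out <- attenuate_background(v, make_full_mask(c(40, 40, 40)), 18)
  expect_equal(max(out$data), 0)
  expect_error(attenuate_background(v, make_full_mask(c(40, 40, 40)), 0.5),
               "radius")
  expect_error(attenuate_background(v, seg_mask(array(TRUE, c(4, 4, 4)), 1.8)),
               "aligned")
})

test_that("top-hat keeps small bright balls and suppresses thick slabs", {
  dims <- c(64, 64, 64)
  ctr <- lymphnet3d:::vox_um(as.matrix(expand.grid(1:64, 1:64, 1:64)),
                             rep(1.8, 3), c(0, 0, 0))
  d2 <- rowSums(sweep(ctr, 2, rep(57.6, 3))^2)
  a <- array(20, dims); a[d2 <= 8^2] <- 120
  th <- attenuate_background(volume3d(a, 1.8), make_full_mask(dims), 18)
  expect_gt(max(th$data[d2 <= 4^2]), 95)         # ~ its 100 contrast
  expect_equal(max(th$data[d2 > 30^2]), 0)       # flat background removed
  # a slab thicker than the 36 um ball diameter is background
  a <- array(20, dims); a[, 20:50, ] <- 120
  th <- attenuate_background(volume3d(a, 1.8), make_full_mask(dims), 18)
  expect_lt(max(th$data), 1e-9)
})

test_that("morphological opening matches the direct oracle", {
  set.seed(20)
  a <- array(runif(20^3, 0, 100), c(20, 20, 20))
  for (erode in c(TRUE, FALSE)) {
    got <- lymphnet3d:::cpp_morph_ball(as.double(a), dim(a), c(3L, 3L, 3L), erode)
    want <- oracle_morph_ball(a, c(3, 3, 3), erode)
    expect_equal(array(got, dim(a)), want)
  }
})

test_that("detection validates sensitivity and is deterministic", {
  set.seed(21)
  a <- array(runif(24^3, 0, 5), c(24, 24, 24))
  v <- volume3d(a, 1.8)
  m <- make_full_mask(dim(a))
  expect_error(detect_valve_blobs(v, m, sensitivity = 1.5), "sensitivity")
  expect_identical(detect_valve_blobs(v, m), detect_valve_blobs(v, m))
})

test_that("a constant enhanced image yields no valves", {
  v <- volume3d(array(7, c(32, 32, 32)), 1.8)
  expect_equal(nrow(detect_valve_blobs(v, make_full_mask(c(32, 32, 32)))), 0)
  v0 <- volume3d(array(0, c(32, 32, 32)), 1.8)
  expect_equal(nrow(detect_valve_blobs(v0, make_full_mask(c(32, 32, 32)))), 0)
})

test_that("an isolated bright blob is found once with an accurate centroid", {
  dims <- c(64, 64, 64)
  ctr <- lymphnet3d:::vox_um(as.matrix(expand.grid(1:64, 1:64, 1:64)),
                             rep(1.8, 3), c(0, 0, 0))
  d2 <- rowSums(sweep(ctr, 2, rep(57.6, 3))^2)
  a <- array(0, dims)
  a[d2 <= 8^2] <- 160                            # true volume ~2145 um^3
  vl <- detect_valve_blobs(volume3d(a, 1.8), make_full_mask(dims))
  expect_equal(nrow(vl), 1)
  expect_lt(sqrt(sum((c(vl$z_um, vl$y_um, vl$x_um) - 57.6)^2)), 2)
  # the measured component volume respects the gate
  expect_gte(vl$volume_um3, 1e3)
  expect_lte(vl$volume_um3, 1e4)
})

test_that("components outside the volume gate are never returned", {
  # property over random blobby fields: every returned volume is in-gate
  set.seed(22)
  for (rep in 1:3) {
    a <- array(0, c(40, 40, 40))
    for (k in 1:6) {
      c0 <- runif(3, 10, 60)
      r0 <- runif(1, 3, 12)
      ctr <- lymphnet3d:::vox_um(as.matrix(expand.grid(1:40, 1:40, 1:40)),
                                 rep(1.8, 3), c(0, 0, 0))
      a[rowSums(sweep(ctr, 2, c0)^2) <= r0^2] <- 150
    }
    vl <- detect_valve_blobs(volume3d(a, 1.8), make_full_mask(c(40, 40, 40)))
    if (nrow(vl)) {
      expect_true(all(vl$volume_um3 >= 1e3 & vl$volume_um3 <= 1e4))
      expect_equal(vl$volume_um3, vl$voxel_count * 1.8^3)
    }
  }
})

test_that("the volume gate brackets measured component volumes", {
  # direct gate semantics on unambiguous binary blobs (no threshold effects):
  # a 100-voxel and a 2000-voxel component at 1.8 um (583 / 11665 um^3)
  # are rejected, a 600-voxel component (3499 um^3) is accepted
  a <- array(0, c(30, 30, 60))
  a[1:10, 1:10, 1] <- 900                         # 100 voxels
  a[1:10, 1:10, 20:39] <- 900                     # 2000 voxels
  a[1:10, 1:6, 50:59] <- 900                      # 600 voxels
  vl <- detect_valve_blobs(volume3d(a, 1.8), make_full_mask(c(30, 30, 60)),
                           sigma_vox = 0, window_vox = 15)
  expect_equal(nrow(vl), 1)
  expect_equal(vl$voxel_count, 600L)
})

test_that("valve positions follow the junction / branch / link rules", {
  spec <- build_network_spec(small_phantom_params(), seed = 1)
  g <- true_graph(spec, z_bands_um = c(120, 190))
  caps <- which(g$edges$class == "capillary_branch")
  links <- which(g$edges$class == "precollector_link")
  expect_gt(length(caps), 0); expect_gt(length(links), 0)

  place <- function(edge_row, frac) {
    p <- g$paths[[edge_row]]
    arc <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
    i <- which.min(abs(arc - frac * max(arc)))
    p[i, ]
  }
  tv <- lymphnet3d:::valve_table(4)
  mid_cap <- place(caps[1], 0.5)                 # mid-capillary
  base_cap <- place(caps[1], 0.08)               # ~10 um from the base node
  mid_link <- place(links[which.max(g$edges$length_um[links])], 0.5)
  tv[1, c("z_um", "y_um", "x_um")] <- as.list(mid_cap)
  tv[2, c("z_um", "y_um", "x_um")] <- as.list(base_cap)
  tv[3, c("z_um", "y_um", "x_um")] <- as.list(mid_link)
  tv[4, c("z_um", "y_um", "x_um")] <- list(10, 10, 10)   # far from everything
  out <- classify_valve_positions(tv, g, 20)
  expect_equal(out$position_class[1], "within_capillary")
  expect_equal(out$position_class[2], "base_of_capillary")
  expect_equal(out$position_class[3], "precollector")
  expect_equal(out$position_class[4], "unassigned")

  # collector call requires the edge's layer
  coll <- which(g$edges$class %in% c("precollector_link", "border_ambiguous",
                                     "cropped_precollector") & g$edges$layer == 3)
  expect_gt(length(coll), 0)
  tv2 <- lymphnet3d:::valve_table(1)
  tv2[1, c("z_um", "y_um", "x_um")] <- as.list(place(coll[1], 0.5))
  expect_equal(classify_valve_positions(tv2, g, 20)$position_class, "collector")
})

test_that("an empty graph leaves all valves unassigned", {
  tv <- lymphnet3d:::valve_table(2)
  g <- lymphnet3d:::empty_graph()
  expect_true(all(classify_valve_positions(tv, g)$position_class == "unassigned"))
})

test_that("layer assignment follows the half-open depth bands", {
  tv <- lymphnet3d:::valve_table(4)
  tv$z_um <- c(140, 150, 209.99, 240)
  out <- assign_layers(tv, c(150, 210))
  expect_equal(out$layer, c(1L, 2L, 2L, 3L))
  expect_error(assign_layers(tv, c(210, 150)), "sorted")

  # edges use the median z of their path
  spec <- build_network_spec(small_phantom_params(), seed = 1)
  g <- assign_layers(true_graph(spec), c(150, 210))
  coll <- which(spec$segments$type == "collector")
  expect_true(all(g$edges$layer[coll] == 3L))    # collectors at 230 um
})
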