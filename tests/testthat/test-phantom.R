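test_that("an empty parameter set yields an empty spec", {
  spec <- build_network_spec(phantom_params(n_capillaries = 0, n_collectors = 0),
                             seed = 1)
  expect_equal(nrow(spec$segments), 0)
  expect_equal(nrow(spec$valves), 0)
  am <- analytic_metrics(spec)
  expect_equal(am$volume_density, 0)
  expect_equal(am$length_density_mm_per_mm3, 0)
  expect_equal(am$valve_density_per_mm3, 0)
})

test_that("fixed 30 um spacing on a 150 um precollector places 4 valves", {
  p2 <- phantom_params(box_um = c(240, 170, 170),
                       plexus_lines_um = c(10, 160),
                       n_capillaries = 0, n_collectors = 0,
                       n_distractors = 0,
                       precollector_valve_spacing_um = 30)
  spec2 <- build_network_spec(p2, seed = 1)
  # interior spans are 150 um; each gets valves at 30, 60, 90, 120
  pre <- which(spec2$segments$type == "precollector")
  span_len <- vapply(pre, function(i) lymphnet3d:::seg_length(spec2, i), numeric(1))
  long <- pre[abs(span_len - 150) < 1e-9]
  expect_gt(length(long), 0)
  for (i in long) {
    arcs <- sort(spec2$valves$arc_um[spec2$valves$seg_id == i])
    expect_equal(arcs, c(30, 60, 90, 120))
  }
})

test_that("spec generation is deterministic and validated", {
  p <- small_phantom_params()
  s1 <- build_network_spec(p, seed = 3)
  s2 <- build_network_spec(p, seed = 3)
  expect_identical(s1, s2)
  s3 <- build_network_spec(p, seed = 4)
  expect_false(identical(s1$nodes, s3$nodes))
  # every capillary's deep end joins a precollector node
  caps <- which(s1$segments$type == "capillary")
  pre_nodes <- unique(unlist(s1$segments[s1$segments$type == "precollector",
                                         c("from", "to")]))
  expect_true(all(s1$segments$from[caps] %in% pre_nodes))
  # capillary tips are open-ended (degree 1)
  deg <- tabulate(c(s1$segments$from, s1$segments$to), nbins = nrow(s1$nodes))
  expect_true(all(deg[s1$segments$to[caps]] == 1))
  # valve arcs inside their edges
  for (i in seq_len(nrow(s1$valves)))
    expect_lte(s1$valves$arc_um[i],
               lymphnet3d:::seg_length(s1, s1$valves$seg_id[i]))
})

test_that("a box too small for the requested counts errors", {
  expect_error(build_network_spec(phantom_params(n_capillaries = 100), 1),
               "box too small")
})

test_that("noiseless single-tube render takes exactly two values", {
  p <- phantom_params(box_um = c(120, 120, 200), plexus_lines_um = numeric(0),
                      n_capillaries = 0, n_collectors = 1, n_distractors = 0,
                      collector_z_um = 60, collector_valve_spacing_um = NULL,
                      background_level = 0, depth_gradient = 0, noise_sigma = 0)
  spec <- build_network_spec(p, seed = 1)
  r <- render_volume(spec, 1.8)
  expect_setequal(unique(as.numeric(r$volume$data)), c(0, 100))
  # labels are noise-free and coincide with the intensity support
  expect_identical(r$truth$label_volume$data > 0, r$volume$data > 0)
})

test_that("rendering is bit-identical for a fixed spec and spacing", {
  spec <- build_network_spec(small_phantom_params(), seed = 5)
  r1 <- render_volume(spec, 3.6)
  r2 <- render_volume(spec, 3.6)
  expect_identical(r1$volume$data, r2$volume$data)
  expect_identical(r1$truth$label_volume$data, r2$truth$label_volume$data)
})

test_that("ground truth records analytic ellipsoid volumes", {
  p <- small_phantom_params(valve_semi_axes_um = c(8, 6, 6))
  spec <- build_network_spec(p, seed = 1)
  tv <- true_valves(spec)
  expect_true(all(abs(tv$volume_um3 - 4 / 3 * pi * 8 * 6 * 6) < 1e-9))
  expect_equal(round(tv$volume_um3[1]), 1206)
})

test_that("valve labels form one component per valve (label conservation)", {
  spec <- build_network_spec(small_phantom_params(noise_sigma = 0), seed = 2)
  r <- render_volume(spec, 2.4)
  lab <- r$truth$label_volume$data
  n_cc <- max(oracle_label(lab == 2, 26))
  expect_equal(n_cc, nrow(spec$valves))
})

test_that("foreground component count matches the spec connectivity", {
  spec <- build_network_spec(small_phantom_params(noise_sigma = 0), seed = 2)
  r <- render_volume(spec, 2.4)
  fg <- r$truth$label_volume$data > 0
  n_cc <- max(oracle_label(array(fg, dim(r$volume$data)), 26))
  # the network is connected by construction; each distractor is separate
  expect_equal(n_cc, 1 + nrow(spec$distractors))
})

test_that("warnings fire for coarse rendering and errors for NaN", {
  spec <- build_network_spec(small_phantom_params(), seed = 1)
  expect_warning(render_volume(spec, 25), "coarser")
  spec_bad <- spec
  spec_bad$intensities$vessel <- NaN
  expect_error(render_volume(spec_bad, 2.4), "non-finite")
})

test_that("analytic metrics match closed forms for a single tube", {
  # one tube of length 1000 um, radius 10, alone in a 1 mm^3 box
  p <- phantom_params(box_um = c(100, 100, 1000), plexus_lines_um = numeric(0),
                      n_capillaries = 0, n_collectors = 1, n_distractors = 0,
                      collector_z_um = 50, collector_radius_um = 10,
                      collector_valve_spacing_um = NULL, noise_sigma = 0)
  p$box_um <- c(1000, 1000, 1000)
  p$collector_z_um <- 500
  spec <- build_network_spec(p, seed = 1)
  am <- analytic_metrics(spec)
  expect_equal(am$length_density_mm_per_mm3, 1, tolerance = 1e-9)
  expect_equal(am$volume_density, pi * 100 * 1000 / 1e9, tolerance = 0.02)
})

test_that("valve density is count over box volume", {
  spec <- build_network_spec(small_phantom_params(), seed = 1)
  am <- analytic_metrics(spec)
  expect_equal(am$valve_density_per_mm3,
               nrow(spec$valves) / (prod(spec$box_um) / 1e9))
})

test_that("rasterized foreground volume approaches the analytic volume", {
  # fine spacing (<= radius/4) on a simple overlap-free tube
  p <- phantom_params(box_um = c(80, 80, 300), plexus_lines_um = numeric(0),
                      n_capillaries = 0, n_collectors = 1, n_distractors = 0,
                      collector_z_um = 40, collector_radius_um = 12,
                      collector_valve_spacing_um = NULL, noise_sigma = 0,
                      background_level = 0, depth_gradient = 0)
  spec <- build_network_spec(p, seed = 1)
  r <- render_volume(spec, 2.5)
  raster <- sum(r$truth$label_volume$data > 0) * 2.5^3
  expect_lt(abs(raster - analytic_metrics(spec)$volume_density * prod(spec$box_um)) /
              raster, 0.05)
})
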