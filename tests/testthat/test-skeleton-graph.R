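test_that("a single foreground voxel is its own skeleton", {
  a <- array(FALSE, c(5, 5, 5)); a[3, 3, 3] <- TRUE
  sk <- skeletonize(seg_mask(a, 1.8))
  expect_equal(nrow(sk$coords), 1)
  expect_equal(unname(sk$coords[1, ]), c(3L, 3L, 3L))
})

test_that("a solid tube thins to a single path with two endpoints", {
  sk <- skeletonize(phantom_tube_mask(radius_vox = 4, length_vox = 50))
  nb <- lengths(lymphnet3d:::skeleton_neighbors(sk$coords, sk$dim))
  expect_equal(sum(nb == 1), 2)          # exactly 2 endpoint voxels
  expect_true(all(nb <= 2))              # a pure path, no junctions
  topo <- skeleton_topology(sk$coords, sk$dim)
  expect_equal(unname(topo), c(1, 0))    # one component, no cycles
})

test_that("skeletonization preserves topology on the constructed suite", {
  cases <- list(tube = list(phantom_tube_mask(3, 30), c(1, 0)),
                y = list(phantom_y_mask(), c(1, 0)),
                h = list(phantom_h_mask(), c(1, 0)),
                torus = list(phantom_torus_mask(), c(1, 1)))
  for (nm in names(cases)) {
    m <- cases[[nm]][[1]]
    sk <- skeletonize(m)
    expect_true(all(m$data[sk$coords]), info = nm)   # skeleton within mask
    topo <- skeleton_topology(sk$coords, sk$dim)
    expect_equal(unname(topo), cases[[nm]][[2]], info = nm)
    expect_equal(max(oracle_label(m$data, 26)), topo[["components"]], info = nm)
  }
})

test_that("skeletonization is deterministic", {
  m <- phantom_tube_mask(4, 40)
  expect_identical(skeletonize(m)$coords, skeletonize(m)$coords)
})

test_that("a 30-voxel straight path becomes 2 nodes and 1 edge of 52.2 um", {
  a <- array(FALSE, c(34, 5, 5)); a[3:32, 3, 3] <- TRUE
  g <- skeleton_to_graph(skeletonize(seg_mask(a, 1.8)), 10)
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$length_um, 29 * 1.8, tolerance = 1e-9)
})

test_that("the Y phantom yields 4 nodes, 3 edges of ~40 um, all branches", {
  g <- classify_edges(skeleton_to_graph(skeletonize(phantom_y_mask()), 10))
  expect_equal(nrow(g$nodes), 4)
  expect_equal(nrow(g$edges), 3)
  expect_true(all(abs(g$edges$length_um - 40) < 4))
  expect_equal(sort(g$nodes$degree), c(1L, 1L, 1L, 3L))
  expect_true(all(g$edges$class == "capillary_branch"))
})

test_that("the H phantom yields 6 nodes, 5 edges, 4 branches + 1 link", {
  g <- classify_edges(skeleton_to_graph(skeletonize(phantom_h_mask()), 10))
  expect_equal(nrow(g$nodes), 6)
  expect_equal(nrow(g$edges), 5)
  expect_equal(sum(g$edges$class == "capillary_branch"), 4)
  expect_equal(sum(g$edges$class == "precollector_link"), 1)
})

test_that("sub-10 um spurs are eliminated by the convergence iteration", {
  m <- phantom_y_mask()
  a <- m$data
  # a ~5 um spur: 3 voxels branching off one arm
  a[30, 40, 33] <- TRUE; a[29, 41, 34] <- TRUE
  g <- skeleton_to_graph(skeletonize(seg_mask(a, 1.8)), 10)
  expect_equal(nrow(g$nodes), 4)
  expect_equal(nrow(g$edges), 3)
})

test_that("a pure cycle is represented as one node with a self-loop", {
  g <- skeleton_to_graph(skeletonize(phantom_torus_mask()), 10)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$from, g$edges$to)
  expect_gt(g$edges$length_um, 80)
})

test_that("an isolated single edge classifies as a capillary branch", {
  a <- array(FALSE, c(30, 5, 5)); a[3:28, 3, 3] <- TRUE
  g <- classify_edges(skeleton_to_graph(skeletonize(seg_mask(a, 1.8)), 10))
  expect_equal(g$edges$class, "capillary_branch")
})

test_that("an empty skeleton yields an empty graph, not an error", {
  sk <- skeletonize(seg_mask(array(FALSE, c(4, 4, 4)), 1.8))
  g <- skeleton_to_graph(sk, 10)
  expect_equal(nrow(g$nodes), 0)
  expect_equal(nrow(g$edges), 0)
})

test_that("graph length is conserved against the skeleton on clean phantoms", {
  m <- phantom_tube_mask(3, 45)
  sk <- skeletonize(m)
  g <- skeleton_to_graph(sk, 10)
  skel_len <- sum(sqrt(rowSums((diff(sk$coords[order(sk$coords[, 3]), ]) * 1.8)^2)))
  expect_lt(abs(sum(g$edges$length_um) - skel_len) / skel_len, 0.01)
})

test_that("border rules classify by length with the ambiguous middle class", {
  spacing <- 1.8
  a <- array(FALSE, c(40, 40, 220))
  a[20, 20, 1:12] <- TRUE                      # ~20 um, touches x face
  a[30, 30, 1:60] <- TRUE                      # ~106 um, touches x face
  a[10, 10, 1:200] <- TRUE                     # ~358 um, touches x face
  a[25, 25, 100:130] <- TRUE                   # ~54 um interior edge
  g <- classify_edges(skeleton_to_graph(skeletonize(seg_mask(a, spacing)), 10))
  g <- apply_border_rules(g)
  cls <- g$edges$class[order(g$edges$length_um)]
  expect_equal(cls, c("discarded", "capillary_branch", "border_ambiguous",
                      "cropped_precollector"))
  # degrees count non-discarded edges only
  expect_equal(sum(g$nodes$degree), 2L * sum(g$edges$class != "discarded"))
})

test_that("adjacency matrix is symmetric and counts incidences", {
  g <- classify_edges(skeleton_to_graph(skeletonize(phantom_h_mask()), 10))
  A <- adjacency_matrix(g)
  expect_true(Matrix::isSymmetric(A))
  expect_equal(sum(A) / 2, nrow(g$edges))
})

test_that("graph exports produce readable CSV and GraphML", {
  g <- classify_edges(skeleton_to_graph(skeletonize(phantom_y_mask()), 10))
  pre <- file.path(withr::local_tempdir(), "g")
  write_graph_csv(g, pre, config_md5 = "abc")
  nodes <- read.csv(paste0(pre, "_nodes.csv"))
  expect_equal(nrow(nodes), 4)
  expect_true(all(nodes$config_md5 == "abc"))
  gml <- paste0(pre, ".graphml")
  write_graphml(g, gml)
  ig <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(ig), 4)
  expect_equal(igraph::gsize(ig), 3)
})
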