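# annular mesh generation: geometry, topology, determinism, connectivity

test_that("single-cell mesh satisfies its geometric invariants", {
  m <- build_single_cell_mesh(5, 0.4, seed = 0)
  # identity deformation: all stretches 1, all J = 1
  cfg <- network_config(m)
  expect_equal(fiber_stretches(m, cfg), rep(1, nrow(m$edges)))
  expect_equal(element_jacobians(m, cfg), rep(1, nrow(m$triangles)))
  expect_true(all(m$tri_area > 0))
  # cavity nodes on the unit circle to 1e-9 r_c
  onb <- m$boundary == "cell_boundary_1"
  expect_true(all(abs(sqrt(rowSums(m$nodes[onb, ]^2)) - 1) < 1e-9))
  out <- m$boundary == "outer_boundary"
  expect_true(all(abs(sqrt(rowSums(m$nodes[out, ]^2)) - 5) < 1e-9 * 5))
  # no duplicate edges; every edge belongs to at least one triangle
  ek <- paste(m$edges[, 1], m$edges[, 2])
  expect_equal(anyDuplicated(ek), 0L)
  em <- rbind(m$triangles[, 1:2], m$triangles[, 2:3], m$triangles[, c(3, 1)])
  tk <- unique(paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2])))
  expect_setequal(ek, tk)
  # total area within 2% of the annulus (boundary faceting)
  expect_equal(sum(m$tri_area), pi * (25 - 1), tolerance = 0.02)
  # Euler relation for a disk with one hole
  expect_equal(nrow(m$nodes) - nrow(m$edges) + nrow(m$triangles), 0L)
})

test_that("meshes are deterministic under a fixed seed and quasi-uniform", {
  m1 <- build_single_cell_mesh(5, 0.4, seed = 0)
  m2 <- build_single_cell_mesh(5, 0.4, seed = 0)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$triangles, m2$triangles)
  m3 <- build_single_cell_mesh(5, 0.4, seed = 1)
  expect_false(isTRUE(all.equal(m1$nodes, m3$nodes)))
  # interior coordination around 6, within [5, 7]
  mc <- mean_coordination(build_single_cell_mesh(10, 0.3, seed = 1),
                          "interior")
  expect_gt(mc, 5); expect_lt(mc, 7)
  expect_equal(mc, 6, tolerance = 0.05)
})

test_that("two-cell meshes have disjoint tagged cavities and reject bad geometry", {
  m <- build_two_cell_mesh(8, 6, 0.4, seed = 0)
  b1 <- m$boundary == "cell_boundary_1"
  b2 <- m$boundary == "cell_boundary_2"
  expect_gt(sum(b1), 8); expect_gt(sum(b2), 8)
  d1 <- sqrt((m$nodes[b1, 1] + 3)^2 + m$nodes[b1, 2]^2)
  d2 <- sqrt((m$nodes[b2, 1] - 3)^2 + m$nodes[b2, 2]^2)
  expect_true(all(abs(c(d1, d2) - 1) < 1e-9))
  expect_equal(m$cell_centers, matrix(c(-3, 0, 3, 0), 2, 2, byrow = TRUE))
  # Euler relation for two holes
  expect_equal(nrow(m$nodes) - nrow(m$edges) + nrow(m$triangles), -1L)
  # separation 4 is valid; overlap and missing outer clearance are not
  expect_s3_class(build_two_cell_mesh(8, 4, 0.4, seed = 0), "fiber_mesh")
  expect_error(build_two_cell_mesh(8, 1.5, 0.4, seed = 0), "overlap")
  expect_error(build_two_cell_mesh(4, 5, 0.4, seed = 0), "clearance|outer")
  expect_error(build_single_cell_mesh(5, 0.9, seed = 0), "fewer than 8")
})

test_that("connectivity reduction hits the target and protects structure", {
  m <- build_single_cell_mesh(5, 0.4, seed = 2)
  C0 <- mean_coordination(m)
  red <- reduce_connectivity(m, 3.6, seed = 1)
  expect_equal(mean_coordination(red), 3.6, tolerance = 0.11)
  # cavity-boundary fibers all survive
  expect_equal(sum(cavity_edge_mask(red)), sum(cavity_edge_mask(m)))
  # still one connected component
  g <- igraph::graph_from_edgelist(red$edges, directed = FALSE)
  expect_true(igraph::is_connected(g))
  # triangles retain their penalty terms by default
  expect_equal(nrow(red$triangles), nrow(m$triangles))
  red2 <- reduce_connectivity(m, 3.6, seed = 1, retain_penalty = FALSE)
  expect_lt(nrow(red2$triangles), nrow(m$triangles))
  # no-op at the current coordination
  same <- reduce_connectivity(m, C0, seed = 1)
  expect_equal(nrow(same$edges), nrow(m$edges))
  expect_error(reduce_connectivity(m, 2.5, seed = 1), "target_C")
})

test_that("tiny meshes refuse disconnecting removals", {
  toy <- toy_triangle_mesh(toy_triangle())
  # one triangle: C = 2, below the allowed range
  expect_error(reduce_connectivity(toy, 3, seed = 1), "target_C")
})

test_that("internal Delaunay agrees with deldir on a random point set", {
  skip_if_not_installed("deldir")
  set.seed(42)
  pts <- cbind(runif(120), runif(120))
  tri <- fibernet:::.delaunay_cpp(pts)
  # compare edge sets
  em <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  ours <- unique(paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2])))
  dd <- deldir::deldir(pts[, 1], pts[, 2])$delsgs
  theirs <- paste(pmin(dd$ind1, dd$ind2), pmax(dd$ind1, dd$ind2))
  expect_setequal(ours, theirs)
})
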