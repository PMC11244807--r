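# equilibration: boundary conditions, single-spring sanity, continuation

test_that("apply_contraction moves cavity nodes radially and fixes them", {
  m <- small_mesh()
  cfg <- apply_contraction(m, 0.5)
  onb <- m$boundary == "cell_boundary_1"
  expect_true(all(cfg$fixed == onb))
  expect_equal(sqrt(rowSums(cfg$positions[onb, ]^2)),
               rep(0.5, sum(onb)), tolerance = 1e-9)
  # gamma = 0 tags without moving anything
  cfg0 <- apply_contraction(m, 0)
  expect_equal(cfg0$positions, m$nodes)
  # expansion: negative gamma pushes the boundary outward
  cfge <- apply_contraction(m, -0.5)
  expect_equal(sqrt(rowSums(cfge$positions[onb, ]^2)),
               rep(1.5, sum(onb)), tolerance = 1e-9)
  expect_error(apply_contraction(m, 1), "below 1")
})

test_that("a single free node on one linear fiber relaxes to lambda = 1", {
  mesh <- structure(
    list(nodes = rbind(c(0, 0), c(1, 0)),
         edges = matrix(c(1L, 2L), 1, 2),
         edge_length = 1,
         triangles = matrix(integer(0), 0, 3),
         tri_area = numeric(0),
         boundary = rep("interior", 2),
         cell_centers = matrix(numeric(0), 0, 2),
         cell_radius = 1, R = NA_real_, target_edge = NA_real_,
         seed = NA_integer_),
    class = "fiber_mesh")
  cfg <- network_config(mesh, rbind(c(0, 0), c(2, 0)),
                        fixed = c(TRUE, FALSE))
  res <- minimize_network(mesh, cfg, fiber_law("lin"),
                          settings = solver_settings(grad_tol = 1e-10))
  expect_true(res$converged)
  expect_equal(res$stretch, 1, tolerance = 1e-8)
})

test_that("the penalty drives an inverted triangle back to positive J", {
  toy <- toy_triangle()
  m <- toy_triangle_mesh(toy)
  # apex pressed past the mid-plane (J < 0): without the penalty this is in
  # the basin of the mirror-image well at J = -1; the penalty makes
  # inversion so costly that minimization restores positive orientation
  p <- m$nodes
  p[3, 2] <- -0.3 * toy$height0
  cfg <- network_config(m, p, fixed = c(TRUE, TRUE, FALSE))
  res <- minimize_network(m, cfg, toy$law, toy$params,
                          solver_settings(grad_tol = 1e-8))
  expect_true(res$converged)
  expect_gt(res$jacobian, 0)
  expect_equal(res$jacobian, 1, tolerance = 1e-3)  # unforced: J = 1 well
})

test_that("small-contraction sweeps track lambda_min = 1 - gamma", {
  m <- small_mesh(R = 4, edge = 0.4, seed = 1)
  sw <- contraction_sweep(m, fiber_law("lin"), c(0.05, 0.10))
  expect_true(all(sw$diagnostics$converged))
  expect_equal(sw$diagnostics$lambda_min, c(0.95, 0.90), tolerance = 1e-6)
  # minimum attained on the cell boundary
  r <- sw$results[[2]]
  i <- which.min(r$stretch)
  onb <- m$boundary[m$edges[i, ]]
  expect_true(all(startsWith(onb, "cell_boundary")))
  # empty schedule: empty result
  sw0 <- contraction_sweep(m, fiber_law("lin"), numeric(0))
  expect_length(sw0$results, 0)
})

test_that("sweeps satisfy descent, convergence and positivity contracts", {
  m <- small_mesh(R = 4, edge = 0.4, seed = 5)
  for (lab in c("lin", "2-7")) {
    sw <- contraction_sweep(m, fiber_law(lab), seq(0.1, 0.5, by = 0.1))
    d <- sw$diagnostics
    expect_true(all(d$converged), info = lab)
    # warm-start energy at each level bounds the converged energy
    expect_true(all(d$energy <= d$warm_energy + 1e-12), info = lab)
    # converged => gradient norm under tolerance
    tol <- 1e-6 * nrow(m$edges) / nrow(m$nodes)
    expect_true(all(d$grad_norm <= tol), info = lab)
    # no inverted element in any converged state
    for (r in sw$results) expect_true(all(r$jacobian > 0), info = lab)
    # penalty clamp never active at convergence
    for (r in sw$results) expect_false(r$clamped, info = lab)
  }
})

test_that("a symmetric patch stays symmetric without perturbation", {
  # regular hexagon + center: contraction of the ring leaves the center put
  ring <- cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6))
  nodes <- rbind(c(0, 0), ring)
  tri <- cbind(1L, 2:7, c(3:7, 2L))
  edges <- unique(t(apply(rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)]),
                          1, sort)))
  mesh <- structure(
    list(nodes = nodes, edges = edges,
         edge_length = sqrt(rowSums((nodes[edges[, 1], ] -
                                     nodes[edges[, 2], ])^2)),
         triangles = tri,
         tri_area = abs(fibernet:::signed_area2(nodes, tri)) / 2,
         boundary = rep("interior", 7),
         cell_centers = matrix(numeric(0), 0, 2),
         cell_radius = 1, R = NA_real_, target_edge = NA_real_,
         seed = NA_integer_),
    class = "fiber_mesh")
  cfg <- network_config(mesh, rbind(c(0, 0), 0.8 * ring),
                        fixed = c(FALSE, rep(TRUE, 6)))
  res <- minimize_network(mesh, cfg, fiber_law("lin"),
                          settings = solver_settings(grad_tol = 1e-10))
  expect_true(res$converged)
  expect_equal(res$config$positions[1, ], c(0, 0), tolerance = 1e-8)
})
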