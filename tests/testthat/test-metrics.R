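# post-processing: densification, decay fits, bands/tethers, onsets, angles

test_that("densification and min-stretch behave on trivial fields", {
  m <- small_mesh()
  r <- fake_result(m)
  d <- densification(r)
  expect_equal(d$rho, rep(1, nrow(m$triangles)))
  expect_equal(d$rho_max, 1)
  expect_equal(min_stretch(r), 1)
  # rho = 1/J pointwise
  r2 <- fake_result(m, jacobian = rep(0.5, nrow(m$triangles)))
  expect_equal(densification(r2)$rho, rep(2, nrow(m$triangles)))
  # inverted elements in a "converged" result are flagged
  bad <- fake_result(m, jacobian = c(-0.2, rep(1, nrow(m$triangles) - 1)))
  expect_warning(densification(bad), "J <= 0")
})

test_that("stretch tree reports distances and radial angles", {
  m <- small_mesh()
  tree <- stretch_tree(fake_result(m))
  expect_equal(tree$stretch, rep(1, nrow(m$edges)))
  mid <- (m$nodes[m$edges[, 1], ] + m$nodes[m$edges[, 2], ]) / 2
  expect_equal(tree$distance, sqrt(rowSums(mid^2)))
  expect_true(all(tree$angle >= 0 & tree$angle <= 90))
  # a purely radial synthetic fiber has angle 0, a tangential one 90
  mesh2 <- equilateral_mesh()
  mesh2$nodes <- rbind(c(1, 0), c(2, 0), c(1.5, 1))
  mesh2$cell_centers <- matrix(c(0, 0), 1, 2)
  t2 <- stretch_tree(fake_result(mesh2), cell_center = c(0, 0))
  expect_equal(t2$angle[1], 0, tolerance = 1e-9)
})

test_that("decay_fit recovers planted power laws over the whole range", {
  m <- build_single_cell_mesh(8, 0.4, seed = 2)
  r0 <- sqrt(rowSums(m$nodes^2))
  for (n_true in c(0.2, 0.5, 1, 1.6, 2)) {
    u <- -0.3 * r0^(-n_true)
    p <- m$nodes * (1 + u / r0)
    fit <- decay_fit(fake_result(m, positions = p))
    expect_equal(fit$n, n_true, tolerance = 1e-6)
    expect_equal(fit$A, 0.3, tolerance = 1e-6)
  }
  # insufficient nodes flagged
  expect_error(decay_fit(fake_result(m), fit_range = c(1.01, 1.02)),
               "usable nodes")
  # non-decaying field flagged: uniform contraction grows |u_r| with r
  expect_warning(decay_fit(fake_result(m, positions = m$nodes * 0.99)),
                 "does not decay")
})

test_that("band and tether detection agree with a brute-force flood fill", {
  m <- small_mesh(R = 3, edge = 0.45, seed = 4)
  K <- nrow(m$triangles)
  set.seed(99)
  for (rep in 1:5) {
    J <- rep(1, K)
    J[sample.int(K, round(0.25 * K))] <- 0.3  # rho ~ 3.3 patches
    r <- fake_result(m, jacobian = J)
    got <- detect_bands(r, 2)$components
    want <- flood_fill_components(m, 1 / J >= 2)
    norm <- function(l) unname(l[order(vapply(l, min, 0))])
    expect_equal(norm(lapply(got, sort)), norm(want))
  }
})

test_that("tether verdicts follow the two-cavity connectivity criterion", {
  m <- build_two_cell_mesh(8, 4.5, 0.45, seed = 1)
  K <- nrow(m$triangles)
  # all rho = 1: no tether
  expect_false(detect_tether(fake_result(m))$tether)
  # hand-built corridor of densified elements joining the two cavities:
  # densify every element in a horizontal strip spanning both cells
  cen <- (m$nodes[m$triangles[, 1], ] + m$nodes[m$triangles[, 2], ] +
          m$nodes[m$triangles[, 3], ]) / 3
  strip <- abs(cen[, 2]) < 0.8
  J <- rep(1, K); J[strip] <- 1 / 3
  tet <- detect_tether(fake_result(m, jacobian = J))
  expect_true(tet$tether)
  expect_true(all(tet$elements %in% which(strip)))
  # breaking the corridor in the middle destroys the tether
  J2 <- J; J2[strip & abs(cen[, 1]) < 0.6] <- 1
  expect_false(detect_tether(fake_result(m, jacobian = J2))$tether)
  # single-cell meshes are rejected
  expect_error(detect_tether(fake_result(small_mesh())), "two-cell")
})

test_that("onset detection fires exactly where the series violate the rules", {
  fake_sweep <- function(gamma, lambda_min, J_min) {
    structure(list(levels = gamma,
                   diagnostics = data.frame(gamma = gamma,
                                            lambda_min = lambda_min,
                                            J_min = J_min)),
              class = "sweep_result")
  }
  g <- seq(0.05, 0.4, by = 0.05)
  # exactly on the boundary line: no onsets
  s1 <- fake_sweep(g, 1 - g, 1 - g)
  o1 <- onset_detection(s1)
  expect_true(is.na(o1$fiber_collapse))
  expect_true(is.na(o1$element_collapse))
  # constructed drop at level 4 in both series
  lam <- 1 - g; lam[4:8] <- lam[4:8] - 0.2
  J <- 1 - g; J[4:8] <- J[4:8] / 2
  o2 <- onset_detection(fake_sweep(g, lam, J))
  expect_equal(o2$fiber_collapse, g[4])
  expect_equal(o2$element_collapse, g[4])
  # invariant to appending post-onset levels
  g3 <- c(g, 0.45, 0.5)
  o3 <- onset_detection(fake_sweep(g3, c(lam, 0.2, 0.2), c(J, 0.15, 0.15)))
  expect_equal(o3$fiber_collapse, o2$fiber_collapse)
  expect_equal(o3$element_collapse, o2$element_collapse)
  expect_error(onset_detection(fake_sweep(g[1:2], lam[1:2], J[1:2])),
               ">= 3 levels")
})

test_that("orientation histograms bin acute angles by tension state", {
  # synthetic star mesh: fibers at controlled angles from the origin
  n <- 36
  ang <- seq(0, pi, length.out = n + 1)[1:n]
  nodes <- rbind(c(0, 0), cbind(cos(ang), sin(ang)))
  mesh <- structure(
    list(nodes = nodes,
         edges = cbind(1L, 2:(n + 1)),
         edge_length = rep(1, n),
         triangles = matrix(integer(0), 0, 3),
         tri_area = numeric(0),
         boundary = rep("interior", n + 1),
         cell_centers = matrix(numeric(0), 0, 2),
         cell_radius = 1, R = NA_real_, target_edge = NA_real_,
         seed = NA_integer_),
    class = "fiber_mesh")
  # stretch half of them (tension), compress the rest
  pos <- nodes
  pos[2:19, ] <- pos[2:19, ] * 1.5
  pos[20:(n + 1), ] <- pos[20:(n + 1), ] * 0.5
  hist <- orientation_histogram(fake_result(mesh, positions = pos),
                                reference = "horizontal")
  expect_equal(sum(hist$tension) + sum(hist$compression), n)
  expect_equal(nrow(hist), 9)
  # all fibers along the reference direction fall in the first bin
  mesh1 <- mesh
  mesh1$edges <- mesh1$edges[1, , drop = FALSE]
  mesh1$edge_length <- 1
  p1 <- nodes; p1[2, ] <- c(2, 0)
  h1 <- orientation_histogram(fake_result(mesh1, positions = p1),
                              reference = "horizontal")
  expect_equal(h1$tension[1], 1)
  # isotropic angles: approximately uniform histogram (chi-square)
  set.seed(5)
  nn <- 10000
  th <- runif(nn, 0, 2 * pi)
  nodes2 <- rbind(c(0, 0), cbind(cos(th), sin(th)))
  mesh2 <- mesh
  mesh2$nodes <- nodes2
  mesh2$edges <- cbind(1L, 2:(nn + 1))
  mesh2$edge_length <- rep(1, nn)
  mesh2$boundary <- rep("interior", nn + 1)
  p2 <- nodes2 * 1.2
  h2 <- orientation_histogram(fake_result(mesh2, positions = p2),
                              reference = "horizontal")
  expect_gt(chisq.test(h2$tension)$p.value, 1e-4)
})
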