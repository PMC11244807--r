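# toy-system oracles: sombrero fiber energy, triangle snap-through

test_that("single-fiber energy surface is a sombrero with minimum circle l0", {
  law <- fiber_law("lin")
  x <- seq(-2.5, 2.5, length.out = 101)
  surf <- single_fiber_energy_surface(law, x, x, l0 = 1)
  # minimum value 0 attained near |x| = l0
  expect_gte(min(surf$energy), 0)
  r <- sqrt(outer(x^2, x^2, `+`))
  on_circle <- abs(r - 1) < 0.03
  expect_lt(min(surf$energy[on_circle]), 1e-3)
  # value at |x| = 2 l0 equals W(2)
  i <- which.min(abs(x - 2)); j <- which.min(abs(x))
  expect_equal(surf$energy[i, j], fiber_energy(law, 2), tolerance = 1e-12)
  # convex along any ray, nonconvex across the origin: the midpoint of two
  # diametrically opposite minima (the origin) has higher energy than both
  expect_gt(fiber_energy(law, 0), 0)
  lamr <- seq(0.01, 3, length.out = 500)
  Wr <- fiber_energy(law, lamr)
  expect_true(all(diff(Wr, differences = 2) > -1e-12))
})

test_that("triangle energy is an even two-well function of J with zeros at +/-1", {
  toy <- toy_triangle(law = fiber_law("lin"))
  hs <- seq(-1.4, 1.4, length.out = 561) * toy$height0
  prof <- triangle_energy_profile(toy, hs)
  expect_equal(prof$J, hs / toy$height0)
  # even in J (without penalty), vanishing exactly at J = +/-1
  rev_E <- rev(prof$energy)
  expect_equal(prof$energy, rev_E, tolerance = 1e-12)
  expect_equal(prof$energy[abs(prof$J - 1) < 1e-9], 0, tolerance = 1e-12)
  expect_equal(prof$energy[abs(prof$J + 1) < 1e-9], 0, tolerance = 1e-12)
  # stationary point at J = 0 that is a local maximum along the path
  mid <- which(abs(prof$J) < 1e-9)
  expect_gt(prof$energy[mid], prof$energy[mid - 40])
  expect_gt(prof$energy[mid], prof$energy[mid + 40])
  # penalty removes the J < 0 well: penalized energy enormous there
  expect_gt(min(prof$penalized_energy[prof$J < -0.5]), 1e3)
})

test_that("the loaded softening triangle is bistable over an interval of forces", {
  # compression-softening sides make the fiber force hump (near J ~ 0.75)
  # well-separated from the penalty wall (near J ~ 0.3), opening a force
  # window with a near-reference AND a penalty-stabilized equilibrium
  toy <- toy_triangle(law = fiber_law("2-7"))
  # zero force: the only stable equilibrium sits at the J = 1 well
  eq0 <- bistable_load_response(toy, 0)
  expect_true(any(eq0$stable & abs(eq0$J - 1) < 0.01))
  expect_false(any(eq0$stable & eq0$J < 0.5))
  forces <- seq(0.05, 0.25, by = 0.005)
  eqs <- bistable_load_response(toy, forces)
  n_stable <- vapply(forces, function(f)
    sum(eqs$stable[eqs$force == f]), 0L)
  expect_gte(sum(n_stable >= 2), 3)
  bi <- eqs[eqs$force == forces[which(n_stable >= 2)[1]] & eqs$stable, ]
  expect_gt(max(bi$J), 0.7)
  expect_lt(min(bi$J), 0.5)
  expect_true(all(eqs$J > 0))
  # between the stable pair sits an unstable equilibrium (snap-through)
  f_bi <- forces[which(n_stable >= 2)[1]]
  un <- eqs[eqs$force == f_bi & !eqs$stable, ]
  expect_true(any(un$J > min(bi$J) & un$J < max(bi$J)))
})

test_that("an isolated family-2 fiber has no stable equilibrium inside (0, lambda*)", {
  law <- fiber_law("2-5")
  lam_star <- critical_stretch(law)
  grid <- seq(1e-3, lam_star - 1e-3, length.out = 500)
  # under prescribed end force, stability requires dS/dlambda > 0
  expect_true(all(fiber_stiffness(law, grid) < 0))
  expect_gt(fiber_stiffness(law, lam_star + 1e-3), 0)
})

test_that("toy profile equals the network energy of a 1-triangle mesh", {
  for (lab in c("lin", "2-7")) {
    toy <- toy_triangle(base = 1.3, law = fiber_law(lab))
    m <- toy_triangle_mesh(toy)
    hs <- seq(0.05, 1.3, length.out = 40) * toy$height0
    prof <- triangle_energy_profile(toy, hs)
    E_net <- vapply(hs, function(h) {
      p <- m$nodes
      p[3, 2] <- h
      total_energy(m, network_config(m, p), toy$law, toy$params)
    }, 0)
    expect_equal(prof$penalized_energy, E_net, tolerance = 1e-12,
                 info = lab)
  }
})

test_that("fiber collapse forces element area collapse, not conversely", {
  # |J| is bounded by the collapsing side: area <= (1/2) c * height_max
  toy <- toy_triangle()
  m <- toy_triangle_mesh(toy)
  # shrink one side to near zero by moving node 2 onto node 1
  p <- m$nodes
  p[2, ] <- p[1, ] + c(1e-3, 0)
  J <- element_jacobians(m, network_config(m, p))
  expect_lt(abs(J), 5e-3)
  # converse: collapse the area with all sides of O(1) length (flat triangle)
  p2 <- m$nodes
  p2[3, ] <- c(0.5, 1e-3)
  J2 <- element_jacobians(m, network_config(m, p2))
  lam2 <- fiber_stretches(m, network_config(m, p2))
  expect_lt(abs(J2), 5e-3)
  expect_true(all(lam2 > 0.45))
})
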