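#' Elementary instability oracles
#'
#' Two toy systems isolate the instability mechanisms of the full network:
#' the sombrero-shaped energy of a single fiber (nonconvexity from large
#' rotations) and the snap-through of a single triangular element
#' (two-well energy in the oriented area ratio `J`, restabilized by the
#' penalty). They double as analytic cross-checks for the network energy
#' code.
#'
#' @name elementary_instabilities
NULL

#' Energy field of a single fiber over endpoint positions
#'
#' One endpoint is fixed; the energy `W(|x| / l0)` is sampled over a grid of
#' positions of the other endpoint. The minimum locus is the circle of
#' radius `l0`: a surface of revolution of a convex 1D well, hence nonconvex
#' in 2D.
#'
#' @param law a [fiber_law()].
#' @param x,y grid coordinates of the moving endpoint (the fixed endpoint
#'   sits at the origin).
#' @param l0 relaxed fiber length.
#' @return a list with `x`, `y` and the `length(x) x length(y)` energy
#'   matrix.
#' @export
single_fiber_energy_surface <- function(law, x, y, l0 = 1) {
  r <- sqrt(outer(x^2, y^2, `+`))
  list(x = x, y = y, energy = fiber_energy(law, r / l0))
}

#' A one-degree-of-freedom triangular element
#'
#' An isoceles triangle of three fibers with fixed base; the apex moves
#' along the symmetry axis, so the oriented area ratio is
#' `J = height / height0`. The reference apex height gives `J = 1`.
#'
#' @param base fixed base length.
#' @param height0 reference apex height (default: equilateral).
#' @param law a [fiber_law()].
#' @param params a [penalty_params()].
#' @export
toy_triangle <- function(base = 1, height0 = base * sqrt(3) / 2,
                         law = fiber_law("lin"),
                         params = penalty_params()) {
  stopifnot(base > 0, height0 > 0)
  structure(list(base = base, height0 = height0, law = law, params = params,
                 side0 = sqrt((base / 2)^2 + height0^2),
                 area0 = base * height0 / 2),
            class = "toy_triangle")
}

toy_side_length <- function(toy, h) sqrt((toy$base / 2)^2 + h^2)

toy_energy <- function(toy, h, penalized = TRUE) {
  lam <- toy_side_length(toy, h) / toy$side0
  E <- 2 * fiber_energy(toy$law, lam)  # base fiber stays at lambda = 1
  if (penalized)
    E <- E + toy$area0 * area_penalty(h / toy$height0, toy$params)
  E
}

toy_energy_deriv <- function(toy, h, penalized = TRUE) {
  L <- toy_side_length(toy, h)
  lam <- L / toy$side0
  dE <- 2 * fiber_force(toy$law, lam) * h / (toy$side0 * L)
  if (penalized) {
    J <- h / toy$height0
    dE <- dE - toy$params$Q * toy$area0 *
      area_penalty(J, toy$params) / toy$height0
  }
  dE
}

#' Energy of the toy triangle along its snap-through path
#'
#' Total fiber energy (and, optionally, penalized energy) of the triangle as
#' the apex moves along the symmetry axis. Without the penalty the curve is
#' an even two-well function of `J` vanishing at `J = +/-1` (the mirror
#' image of the reference triangle is also unstretched); the unpenalized
#' stationary point at `J = 0` is a local maximum along the path. The
#' penalty removes the `J < 0` well and creates a penalty-stabilized
#' compressed well at small positive `J`.
#'
#' @param toy a [toy_triangle()].
#' @param apex_heights signed apex heights to sample.
#' @return data frame with `height`, `J`, `energy` (fibers only) and
#'   `penalized_energy`.
#' @export
triangle_energy_profile <- function(toy, apex_heights) {
  data.frame(
    height = apex_heights,
    J = apex_heights / toy$height0,
    energy = vapply(apex_heights, function(h)
      toy_energy(toy, h, penalized = FALSE), 0),
    penalized_energy = vapply(apex_heights, function(h)
      toy_energy(toy, h, penalized = TRUE), 0))
}

#' Equilibria of the loaded toy triangle
#'
#' For each compressive force `f` the apex equilibria are the stationary
#' points of `E_pen(h) - f (height0 - h)` along the symmetry axis,
#' classified stable/unstable by the sign of the second derivative. Over a
#' range of forces the element is bistable: a near-reference and a
#' penalty-stabilized collapsed equilibrium coexist, the signature of
#' snap-through.
#'
#' @param toy a [toy_triangle()].
#' @param forces nonnegative compressive forces applied along the axis.
#' @param h_range search interval of apex heights (default spans the
#'   penalty-stabilized well up to above the reference height).
#' @param n_grid scan resolution.
#' @return data frame with one row per equilibrium: `force`, `height`, `J`,
#'   `stable`.
#' @export
bistable_load_response <- function(toy, forces,
                                   h_range = c(1e-4 * toy$height0,
                                               1.6 * toy$height0),
                                   n_grid = 4000) {
  hs <- seq(h_range[1], h_range[2], length.out = n_grid)
  out <- NULL
  for (f in forces) {
    dG <- toy_energy_deriv(toy, hs) + f  # G = E_pen - f (h0 - h)
    sgn <- sign(dG)
    idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    for (i in idx) {
      root <- uniroot(function(h) toy_energy_deriv(toy, h) + f,
                      c(hs[i], hs[i + 1]), tol = 1e-12)$root
      eps <- 1e-6 * toy$height0
      d2 <- (toy_energy_deriv(toy, root + eps) -
             toy_energy_deriv(toy, root - eps)) / (2 * eps)
      out <- rbind(out, data.frame(force = f, height = root,
                                   J = root / toy$height0,
                                   stable = d2 > 0))
    }
  }
  if (is.null(out))
    data.frame(force = numeric(0), height = numeric(0), J = numeric(0),
               stable = logical(0))
  else out
}

#' @importFrom stats uniroot
NULL

#' Realize the toy triangle as a one-triangle mesh
#'
#' Returns a `fiber_mesh` whose penalized network energy restricted to the
#' apex symmetry axis equals [triangle_energy_profile()] exactly; used as a
#' cross-module consistency oracle.
#'
#' @param toy a [toy_triangle()].
#' @export
toy_triangle_mesh <- function(toy) {
  nodes <- rbind(c(0, 0), c(toy$base, 0), c(toy$base / 2, toy$height0))
  structure(
    list(nodes = nodes,
         edges = rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)),
         edge_length = c(toy$base, toy$side0, toy$side0),
         triangles = matrix(c(1L, 2L, 3L), 1, 3),
         tri_area = toy$area0,
         boundary = rep("interior", 3),
         cell_centers = matrix(numeric(0), 0, 2),
         cell_radius = 1, R = NA_real_,
         target_edge = NA_real_, seed = NA_integer_),
    class = "fiber_mesh")
}
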