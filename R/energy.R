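#' Penalty parameters for the oriented-area term
#'
#' Each triangular element contributes `A_k * Phi(J_k)` to the network
#' energy, with `Phi(J) = exp(-Q (J - b))` and `J` the oriented
#' deformed/reference area ratio. `Phi` is negligible for `J > b` and
#' astronomically large for `J < 0`, so it keeps elements from inverting
#' (interpenetration of matter) while leaving ordinary configurations
#' essentially unaffected. Defaults `Q = 50`, `b = 1/4`.
#'
#' @param Q positive decay rate of the exponential penalty.
#' @param b positive offset; the penalty equals 1 at `J = b`.
#' @export
penalty_params <- function(Q = 50, b = 0.25) {
  stopifnot(Q > 0, b > 0)
  structure(list(Q = Q, b = b), class = "penalty_params")
}

#' Evaluate the area penalty function
#'
#' @param J numeric vector of oriented area ratios (any sign).
#' @param params a [penalty_params()].
#' @return `exp(-Q (J - b))`.
#' @export
area_penalty <- function(J, params = penalty_params()) {
  exp(-params$Q * (J - params$b))
}

#' Network configuration: deformed nodal positions plus the fixed/free split
#'
#' @param mesh a `fiber_mesh`.
#' @param positions N x 2 matrix of deformed coordinates (defaults to the
#'   reference configuration).
#' @param fixed logical vector of length N; fixed nodes never move during
#'   minimization.
#' @export
network_config <- function(mesh, positions = mesh$nodes,
                           fixed = rep(FALSE, nrow(mesh$nodes))) {
  stopifnot(is.matrix(positions), ncol(positions) == 2,
            nrow(positions) == nrow(mesh$nodes),
            length(fixed) == nrow(mesh$nodes))
  structure(list(positions = positions, fixed = as.logical(fixed)),
            class = "network_config")
}

# flat DOF vector (x1, y1, x2, y2, ...) <-> N x 2 positions
pos_to_dof <- function(positions) as.vector(t(positions))
dof_to_pos <- function(dof) matrix(dof, ncol = 2, byrow = TRUE)

law_args <- function(law) list(family = law$family, k = law$k)

#' Per-fiber effective stretches of a configuration
#'
#' `lambda_j = |x_i - x_j| / l_ij` for every fiber edge. Coincident
#' endpoints give `lambda = 0` (allowed; all laws have finite energy there).
#'
#' @param mesh a `fiber_mesh`.
#' @param config a [network_config()].
#' @return numeric vector, one stretch per edge.
#' @export
fiber_stretches <- function(mesh, config) {
  p <- config$positions
  d <- p[mesh$edges[, 1], , drop = FALSE] - p[mesh$edges[, 2], , drop = FALSE]
  sqrt(rowSums(d^2)) / mesh$edge_length
}

#' Per-element oriented area ratios
#'
#' `J_k` = deformed over reference signed triangle area, computed with the
#' out-of-plane cross product; negative `J` means the element has inverted.
#'
#' @inheritParams fiber_stretches
#' @return numeric vector, one `J` per triangle.
#' @export
element_jacobians <- function(mesh, config) {
  signed_area2(config$positions, mesh$triangles) / (2 * mesh$tri_area)
}

#' Penalized total network energy and its exact gradient
#'
#' `total_energy` evaluates `E = sum_j W(lambda_j) + sum_k A_k Phi(J_k)`;
#' `energy_gradient` returns its analytic gradient with respect to the free
#' nodal coordinates as a flat DOF vector (`x1, y1, x2, y2, ...`), with
#' zeros at fixed DOFs. The penalty exponent is clamped at 500 during
#' evaluation so line-search trial states cannot overflow; converged
#' solutions never sit at the clamp.
#'
#' @inheritParams fiber_stretches
#' @param law a [fiber_law()].
#' @param params a [penalty_params()].
#' @export
total_energy <- function(mesh, config, law, params = penalty_params()) {
  .net_energy_cpp(pos_to_dof(config$positions),
                  mesh$edges, mesh$edge_length,
                  mesh$triangles, mesh$tri_area,
                  law$family, law$k, params$Q, params$b)
}

#' @rdname total_energy
#' @export
energy_gradient <- function(mesh, config, law, params = penalty_params()) {
  res <- .net_energy_grad_cpp(pos_to_dof(config$positions),
                              mesh$edges, mesh$edge_length,
                              mesh$triangles, mesh$tri_area,
                              law$family, law$k, params$Q, params$b)
  g <- res$gradient
  fixed_dof <- rep(config$fixed, each = 2)
  g[fixed_dof] <- 0
  g
}
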