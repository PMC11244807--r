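#' Solver settings for nonlinear conjugate-gradient minimization
#'
#' Equilibria are local minimizers of the penalized network energy, found by
#' Polak-Ribiere+ nonlinear CG with a strong-Wolfe line search
#' (`c1 = 1e-4`, `c2 = 0.1`) and periodic restarts. Because the energy is
#' nonconvex the result is path-dependent by design: continuation and the
#' symmetry-breaking perturbation select which local minimum is reached.
#'
#' @param grad_tol infinity-norm gradient tolerance; `NULL` (default) uses
#'   the scale-free `1e-6 * F / N` (fibers per node) of the mesh at hand.
#' @param max_iter iteration cap per minimization.
#' @param restart_period CG restart period; `NULL` uses `2 *` number of DOFs.
#' @param perturbation_amplitude symmetry-breaking perturbation applied to
#'   free nodes at the first continuation level, as a fraction of the mean
#'   fiber length (0 disables it).
#' @param perturbation_seed integer seed for that perturbation.
#' @export
solver_settings <- function(grad_tol = NULL, max_iter = 50000L,
                            restart_period = NULL,
                            perturbation_amplitude = 1e-3,
                            perturbation_seed = 1L) {
  if (!is.null(grad_tol)) stopifnot(grad_tol > 0)
  stopifnot(max_iter > 0, perturbation_amplitude >= 0)
  structure(list(grad_tol = grad_tol, max_iter = as.integer(max_iter),
                 restart_period = restart_period,
                 perturbation_amplitude = perturbation_amplitude,
                 perturbation_seed = as.integer(perturbation_seed)),
            class = "solver_settings")
}

resolve_settings <- function(settings, mesh) {
  if (is.null(settings$grad_tol))
    settings$grad_tol <- 1e-6 * nrow(mesh$edges) / nrow(mesh$nodes)
  if (is.null(settings$restart_period))
    settings$restart_period <- 2L * 2L * nrow(mesh$nodes)
  settings
}

#' Prescribe radial cell-boundary contraction
#'
#' Moves every node on a cavity boundary radially toward its own cell
#' center so the cavity radius becomes `(1 - gamma) r_c`, and marks those
#' nodes fixed. Interior nodes and the outer boundary stay free (the outer
#' boundary carries no loads or constraints). Negative `gamma` prescribes
#' radial expansion.
#'
#' @param mesh a `fiber_mesh`.
#' @param gamma fractional cell radius decrease, `gamma < 1`.
#' @return a [network_config()] with attribute `gamma`.
#' @export
apply_contraction <- function(mesh, gamma) {
  if (!is.finite(gamma) || gamma >= 1)
    stop("gamma must be a finite value below 1")
  pos <- mesh$nodes
  fixed <- rep(FALSE, nrow(pos))
  for (i in seq_len(nrow(mesh$cell_centers))) {
    idx <- which(mesh$boundary == paste0("cell_boundary_", i))
    ctr <- mesh$cell_centers[i, ]
    pos[idx, 1] <- ctr[1] + (1 - gamma) * (pos[idx, 1] - ctr[1])
    pos[idx, 2] <- ctr[2] + (1 - gamma) * (pos[idx, 2] - ctr[2])
    fixed[idx] <- TRUE
  }
  cfg <- network_config(mesh, pos, fixed)
  attr(cfg, "gamma") <- gamma
  cfg
}

#' Equilibrate the network by energy minimization
#'
#' Minimizes the penalized energy over the free nodal coordinates from the
#' given initial configuration. Non-convergence within `max_iter` returns
#' `converged = FALSE` with diagnostics rather than an error.
#'
#' @param mesh a `fiber_mesh`.
#' @param config initial [network_config()] (its fixed nodes are the
#'   Dirichlet data and never move).
#' @param law a [fiber_law()].
#' @param params a [penalty_params()].
#' @param settings a [solver_settings()].
#' @return an `equilibrium_result`: the converged configuration, per-fiber
#'   stretches, per-element `J` and densification `rho = 1/J`, final energy,
#'   gradient norm, iteration count and convergence flag.
#' @export
minimize_network <- function(mesh, config, law, params = penalty_params(),
                             settings = solver_settings()) {
  if (all(config$fixed)) stop("configuration has no free node")
  settings <- resolve_settings(settings, mesh)
  free_dof <- rep(!config$fixed, each = 2)
  res <- .nlcg_cpp(pos_to_dof(config$positions), free_dof,
                   mesh$edges, mesh$edge_length,
                   mesh$triangles, mesh$tri_area,
                   law$family, law$k, params$Q, params$b,
                   settings$grad_tol, settings$max_iter,
                   as.integer(settings$restart_period),
                   1e-4, 0.1, 0.1 * mean(mesh$edge_length))
  out_cfg <- network_config(mesh, dof_to_pos(res$positions), config$fixed)
  lam <- fiber_stretches(mesh, out_cfg)
  J <- element_jacobians(mesh, out_cfg)
  structure(
    list(mesh = mesh, law = law, params = params,
         config = out_cfg,
         energy = res$energy,
         grad_norm = res$grad_norm,
         iterations = res$iterations,
         converged = res$converged,
         n_eval = res$n_eval,
         clamped = res$clamped,
         stretch = lam,
         jacobian = J,
         densification = 1 / J,
         gamma = attr(config, "gamma") %||% NA_real_),
    class = "equilibrium_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<equilibrium_result> gamma = %s, E = %.6g, |grad|_rms = %.3g\n",
    "  %s in %d iterations; lambda in [%.3f, %.3f], J_min = %.3f\n"),
    format(x$gamma), x$energy, x$grad_norm,
    if (x$converged) "converged" else "NOT converged", x$iterations,
    min(x$stretch), max(x$stretch), min(x$jacobian)))
  invisible(x)
}

# warm-started configuration at a new contraction level: free nodes keep
# their current positions, cavity nodes move to the new prescribed radius
warm_config <- function(mesh, positions, gamma) {
  bc <- apply_contraction(mesh, gamma)
  pos <- positions
  pos[bc$fixed, ] <- bc$positions[bc$fixed, ]
  cfg <- network_config(mesh, pos, bc$fixed)
  attr(cfg, "gamma") <- gamma
  cfg
}

#' Contraction sweep with warm-started continuation
#'
#' Solves a strictly increasing schedule of contraction levels, each
#' warm-started from the previous equilibrium. The first level starts from
#' the reference configuration with a small seeded random perturbation of
#' the free nodes (amplitude `perturbation_amplitude` x mean fiber length)
#' so the minimizer can leave saddle points, mimicking physical
#' imperfection. A level that fails to converge is re-approached through up
#' to 3 bisected intermediate levels before the sweep aborts with partial
#' results.
#'
#' @param mesh a `fiber_mesh`.
#' @param law a [fiber_law()].
#' @param gamma_schedule strictly increasing contraction levels, each `< 1`.
#' @param params a [penalty_params()].
#' @param settings a [solver_settings()].
#' @return a `sweep_result`: per-level `equilibrium_result`s, the schedule,
#'   and a diagnostics data frame (gamma, iterations, energy, gradient norm,
#'   warm-start energy, `lambda_min`, `J_min`).
#' @export
contraction_sweep <- function(mesh, law, gamma_schedule,
                              params = penalty_params(),
                              settings = solver_settings()) {
  if (length(gamma_schedule) == 0)
    return(structure(list(levels = numeric(0), results = list(),
                          diagnostics = data.frame(), law = law,
                          mesh = mesh, completed = TRUE),
                     class = "sweep_result"))
  if (any(diff(gamma_schedule) <= 0))
    stop("gamma_schedule must be strictly increasing")
  if (any(gamma_schedule >= 1)) stop("contraction levels must be below 1")
  settings <- resolve_settings(settings, mesh)

  pos <- mesh$nodes
  if (settings$perturbation_amplitude > 0) {
    amp <- settings$perturbation_amplitude * mean(mesh$edge_length)
    bc0 <- apply_contraction(mesh, gamma_schedule[1])
    pert <- with_seed(settings$perturbation_seed,
                      matrix(runif(2 * nrow(pos), -amp, amp), ncol = 2))
    pert[bc0$fixed, ] <- 0
    pos <- pos + pert
  }

  results <- vector("list", length(gamma_schedule))
  warm_E <- numeric(length(gamma_schedule))
  completed <- TRUE

  solve_level <- function(gamma, pos) {
    cfg <- warm_config(mesh, pos, gamma)
    list(res = minimize_network(mesh, cfg, law, params, settings),
         warm_energy = total_energy(mesh, cfg, law, params))
  }

  gamma_prev <- 0
  for (i in seq_along(gamma_schedule)) {
    gamma_i <- gamma_schedule[i]
    step <- solve_level(gamma_i, pos)
    if (!step$res$converged) {
      # approach the level through bisected intermediate contractions
      for (halving in seq_len(3)) {
        gam_mid <- gamma_prev + (gamma_i - gamma_prev) / 2^halving
        mid <- solve_level(gam_mid, pos)
        if (mid$res$converged) pos <- mid$res$config$positions
        step <- solve_level(gamma_i, pos)
        if (step$res$converged) break
      }
    }
    results[[i]] <- step$res
    warm_E[i] <- step$warm_energy
    if (!step$res$converged) {
      warning(sprintf("sweep aborted: level gamma = %g did not converge",
                      gamma_i))
      completed <- FALSE
      results <- results[seq_len(i)]
      warm_E <- warm_E[seq_len(i)]
      break
    }
    pos <- step$res$config$positions
    gamma_prev <- gamma_i
  }

  levels <- gamma_schedule[seq_along(results)]
  diagnostics <- data.frame(
    gamma = levels,
    iterations = vapply(results, `[[`, 0, "iterations"),
    energy = vapply(results, `[[`, 0, "energy"),
    warm_energy = warm_E,
    grad_norm = vapply(results, `[[`, 0, "grad_norm"),
    converged = vapply(results, `[[`, TRUE, "converged"),
    lambda_min = vapply(results, function(r) min(r$stretch), 0),
    J_min = vapply(results, function(r) min(r$jacobian), 0))
  structure(list(levels = levels, results = results,
                 diagnostics = diagnostics, law = law, mesh = mesh,
                 completed = completed),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> law %s, %d level(s)%s\n", x$law$label,
              length(x$levels), if (x$completed) "" else " (aborted)"))
  if (length(x$levels)) print(x$diagnostics, row.names = FALSE)
  invisible(x)
}
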