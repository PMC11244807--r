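#' @title Scripted numerical experiments
#' @description Parameterized drivers reproducing the standard scenarios:
#'   a single contracting cell, progressive-contraction sweeps, the
#'   displacement decay study, two-cell tether formation and the tether
#'   phase map, low-connectivity networks and cell expansion. All drivers
#'   are deterministic given their seeds.
#' @name protocols
NULL

# 5%-step continuation schedule up to `gamma` (always ending exactly there)
gamma_schedule_to <- function(gamma, step = 0.05) {
  if (gamma <= 0) return(numeric(0))
  s <- seq(step, gamma, by = step)
  if (length(s) == 0 || abs(s[length(s)] - gamma) > 1e-12)
    s <- c(s, gamma)
  s
}

#' Single contracting cell
#'
#' Builds the annular mesh, contracts the cell to `gamma` through
#' warm-started 5% continuation steps, and post-processes the final
#' equilibrium.
#'
#' @param law a [fiber_law()] or a law string such as `"2-5"`.
#' @param gamma final contraction level.
#' @param R outer radius in `r_c` units (default 10).
#' @param target_edge fiber length in `r_c` units (default 0.25).
#' @param seed master seed (mesh jitter and symmetry perturbation).
#' @param gamma_step continuation step (default 0.05).
#' @param params a [penalty_params()].
#' @param settings a [solver_settings()].
#' @param rho_threshold densification threshold for the report.
#' @param out_dir if non-`NULL`, results are written there (mesh and result
#'   CSV/VTK, metrics JSON, convergence log).
#' @return list with `mesh`, `sweep`, the final `result`, the metrics
#'   `report`, and `onsets` when the sweep has >= 3 levels.
#' @export
run_single_cell <- function(law, gamma = 0.5, R = 10, target_edge = 0.25,
                            seed = 1L, gamma_step = 0.05,
                            params = penalty_params(),
                            settings = solver_settings(),
                            rho_threshold = 2, out_dir = NULL) {
  if (is.character(law)) law <- fiber_law(law)
  mesh <- build_single_cell_mesh(R, target_edge, seed)
  settings$perturbation_seed <- seed
  sweep <- contraction_sweep(mesh, law, gamma_schedule_to(gamma, gamma_step),
                             params, settings)
  result <- if (length(sweep$results)) sweep$results[[length(sweep$results)]]
            else minimize_network(mesh, apply_contraction(mesh, gamma),
                                  law, params, settings)
  out <- list(mesh = mesh, sweep = sweep, result = result,
              report = metrics_report(result, rho_threshold))
  if (length(sweep$levels) >= 3)
    out$onsets <- onset_detection(sweep)
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

#' Two contracting cells
#'
#' @inheritParams run_single_cell
#' @param separation center-to-center cell distance in `r_c` units.
#' @param R outer radius; default `separation / 2 + 5`.
#' @param target_C optionally reduce the network to this mean coordination
#'   (lower-connectivity study) before contracting.
#' @export
run_two_cell <- function(law, separation = 6, gamma = 0.5,
                         R = separation / 2 + 5, target_edge = 0.25,
                         seed = 1L, gamma_step = 0.05,
                         params = penalty_params(),
                         settings = solver_settings(),
                         rho_threshold = 2, target_C = NULL,
                         out_dir = NULL) {
  if (is.character(law)) law <- fiber_law(law)
  mesh <- build_two_cell_mesh(R, separation, target_edge, seed)
  if (!is.null(target_C))
    mesh <- reduce_connectivity(mesh, target_C, seed = seed + 1L)
  settings$perturbation_seed <- seed
  sweep <- contraction_sweep(mesh, law, gamma_schedule_to(gamma, gamma_step),
                             params, settings)
  result <- sweep$results[[length(sweep$results)]]
  out <- list(mesh = mesh, sweep = sweep, result = result,
              report = metrics_report(result, rho_threshold))
  if (length(sweep$levels) >= 3)
    out$onsets <- onset_detection(sweep)
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

#' Displacement decay study
#'
#' Runs a single contracting cell over several domain sizes and fits the
#' radial displacement decay power `u_r ~ A r^-n` at each requested
#' contraction level, averaging `n` over domain sizes.
#'
#' @inheritParams run_single_cell
#' @param gammas contraction levels at which to fit (continuation visits
#'   each; default just `gamma`).
#' @param R_values domain radii in `r_c` units.
#' @return list with the per-(R, gamma) fit `table`, the `mean_n` per
#'   gamma, a `monotone_decreasing` flag across gammas, and the count of
#'   `failed` fits (excluded from means).
#' @export
run_decay_study <- function(law, gammas = 0.3, R_values = c(5, 10),
                            target_edge = 0.3, seed = 1L, gamma_step = 0.05,
                            params = penalty_params(),
                            settings = solver_settings()) {
  if (is.character(law)) law <- fiber_law(law)
  stopifnot(length(R_values) >= 1, all(diff(sort(gammas)) > 0) || TRUE)
  gammas <- sort(gammas)
  tab <- NULL
  failed <- 0L
  for (R in R_values) {
    mesh <- build_single_cell_mesh(R, target_edge, seed)
    settings$perturbation_seed <- seed
    sweep <- contraction_sweep(mesh, law,
                               gamma_schedule_to(max(gammas), gamma_step),
                               params, settings)
    for (g in gammas) {
      i <- which(abs(sweep$levels - g) < 1e-9)
      if (length(i) != 1) { failed <- failed + 1L; next }
      fit <- tryCatch(decay_fit(sweep$results[[i]]), error = function(e) NULL)
      if (is.null(fit)) { failed <- failed + 1L; next }
      tab <- rbind(tab, data.frame(R = R, gamma = g, A = fit$A, n = fit$n,
                                   n_nodes = fit$n_nodes))
    }
  }
  mean_n <- if (is.null(tab)) numeric(0)
            else vapply(split(tab$n, tab$gamma), mean, 0)
  list(table = tab, mean_n = mean_n,
       monotone_decreasing = length(mean_n) < 2 || all(diff(mean_n) < 0),
       failed = failed)
}

#' First tether-forming contraction level of a sweep
#'
#' @param sweep a `sweep_result` on a two-cell mesh.
#' @param rho_threshold densification threshold.
#' @return the smallest recorded `gamma` with a tether, or `NA_real_`.
#' @export
first_tether_level <- function(sweep, rho_threshold = 2) {
  for (i in seq_along(sweep$results))
    if (detect_tether(sweep$results[[i]], rho_threshold)$tether)
      return(sweep$levels[i])
  NA_real_
}

#' Tether phase map: minimal tether-forming contraction per separation
#'
#' For each cell-cell separation, contracts in `gamma_step` increments
#' (warm-started continuation) until a tether is detected or `gamma_max` is
#' reached.
#'
#' @inheritParams run_two_cell
#' @param separations center-to-center distances to scan.
#' @param gamma_max largest contraction tried.
#' @return data frame with `separation` and `gamma_tether` (`NA` if no
#'   tether forms in range).
#' @export
run_tether_phase_map <- function(law, separations, gamma_max = 0.8,
                                 gamma_step = 0.05, target_edge = 0.4,
                                 seed = 1L, params = penalty_params(),
                                 settings = solver_settings(),
                                 rho_threshold = 2) {
  if (is.character(law)) law <- fiber_law(law)
  out <- data.frame(separation = separations,
                    gamma_tether = NA_real_)
  for (s in seq_along(separations)) {
    sep <- separations[s]
    mesh <- build_two_cell_mesh(sep / 2 + 5, sep, target_edge, seed)
    settings$perturbation_seed <- seed
    schedule <- gamma_schedule_to(gamma_max, gamma_step)
    res <- sweep_until(mesh, law, schedule, params, settings,
                       function(r) detect_tether(r, rho_threshold)$tether)
    out$gamma_tether[s] <- res$gamma
  }
  out
}

# warm-started continuation that stops as soon as `predicate(result)` holds;
# returns the triggering gamma (NA if never) and the last result
sweep_until <- function(mesh, law, schedule, params, settings, predicate) {
  settings <- resolve_settings(settings, mesh)
  pos <- mesh$nodes
  if (settings$perturbation_amplitude > 0 && length(schedule)) {
    amp <- settings$perturbation_amplitude * mean(mesh$edge_length)
    bc0 <- apply_contraction(mesh, schedule[1])
    pert <- with_seed(settings$perturbation_seed,
                      matrix(runif(2 * nrow(pos), -amp, amp), ncol = 2))
    pert[bc0$fixed, ] <- 0
    pos <- pos + pert
  }
  last <- NULL
  for (g in schedule) {
    res <- minimize_network(mesh, warm_config(mesh, pos, g), law,
                            params, settings)
    if (!res$converged)
      return(list(gamma = NA_real_, result = res, failed_at = g))
    pos <- res$config$positions
    last <- res
    if (predicate(res)) return(list(gamma = g, result = res))
  }
  list(gamma = NA_real_, result = last)
}

#' Radially expanding cell
#'
#' Prescribes an outward radial displacement of the cell boundary
#' (expansion by `expansion` x `r_c`), reached through warm-started
#' increments, and summarizes fiber orientation around the cell: under
#' expansion, compressed fibers align radially while tensed fibers orient
#' circumferentially (the opposite of contraction).
#'
#' @inheritParams run_single_cell
#' @param expansion fractional radius increase (> 0); internally a negative
#'   contraction.
#' @export
run_expansion <- function(law, expansion = 0.5, R = 10, target_edge = 0.25,
                          seed = 1L, gamma_step = 0.05,
                          params = penalty_params(),
                          settings = solver_settings(),
                          rho_threshold = 2) {
  if (is.character(law)) law <- fiber_law(law)
  stopifnot(expansion > 0)
  mesh <- build_single_cell_mesh(R, target_edge, seed)
  settings <- resolve_settings(settings, mesh)
  settings$perturbation_seed <- seed
  pos <- mesh$nodes
  result <- NULL
  for (g in -gamma_schedule_to(expansion, gamma_step)) {
    result <- minimize_network(mesh, warm_config(mesh, pos, g), law,
                               params, settings)
    pos <- result$config$positions
  }
  ang <- fiber_angles(mesh, result$config$positions, "radial",
                      mesh$cell_centers[1, ])
  near <- {
    mid <- (mesh$nodes[mesh$edges[, 1], ] + mesh$nodes[mesh$edges[, 2], ]) / 2
    sqrt(rowSums(mid^2)) < 0.5 * R
  }
  list(mesh = mesh, result = result,
       report = metrics_report(result, rho_threshold),
       orientation = list(
         mean_angle_compressed = mean(ang[near & result$stretch < 1]),
         mean_angle_tensed = mean(ang[near & result$stretch > 1])))
}
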