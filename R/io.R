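#' @title File output and run configuration
#' @description CSV tables are the canonical machine-readable output;
#'   legacy ASCII VTK unstructured grids serve visualization (ParaView and
#'   friends); metrics go to JSON. Run configurations are flat JSON files
#'   validated against a fixed key set.
#' @name cli_config_io
NULL

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a mesh or result as a legacy ASCII VTK unstructured grid
#'
#' Triangles as VTK cells. For results, points are the deformed positions
#' with a `displacement` point vector field and `J` / `rho` cell fields.
#'
#' @param mesh a `fiber_mesh`.
#' @param path output file path.
#' @export
write_mesh_vtk <- function(mesh, path) {
  write_vtk_impl(mesh, mesh$nodes, path, point_data = NULL, cell_data = NULL)
}

#' @rdname write_mesh_vtk
#' @param result an `equilibrium_result`.
#' @export
write_result_vtk <- function(result, path) {
  mesh <- result$mesh
  u <- result$config$positions - mesh$nodes
  write_vtk_impl(mesh, result$config$positions, path,
                 point_data = list(displacement = u),
                 cell_data = list(J = result$jacobian,
                                  rho = result$densification))
}

write_vtk_impl <- function(mesh, points, path, point_data, cell_data) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(points); m <- nrow(mesh$triangles)
  writeLines(c("# vtk DataFile Version 3.0",
               "fibernet unstructured grid", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(paste(fmt_num(points[, 1]), fmt_num(points[, 2]), "0"), con)
  writeLines(sprintf("CELLS %d %d", m, 4 * m), con)
  writeLines(paste(3, mesh$triangles[, 1] - 1, mesh$triangles[, 2] - 1,
                   mesh$triangles[, 3] - 1), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  if (!is.null(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      writeLines(sprintf("VECTORS %s double", nm), con)
      writeLines(paste(fmt_num(v[, 1]), fmt_num(v[, 2]), "0"), con)
    }
  }
  if (!is.null(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(fmt_num(cell_data[[nm]]), con)
    }
  }
  invisible(path)
}

#' Write mesh tables as CSV
#'
#' `nodes.csv` (id, x, y, boundary), `edges.csv` (id, node1, node2,
#' length), `triangles.csv` (id, node1, node2, node3, area); all floats at
#' full double precision.
#'
#' @param mesh a `fiber_mesh`.
#' @param dir output directory (created if needed).
#' @export
write_mesh_csv <- function(mesh, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(id = seq_len(nrow(mesh$nodes)),
                       x = mesh$nodes[, 1], y = mesh$nodes[, 2],
                       boundary = mesh$boundary),
            file.path(dir, "nodes.csv"), row.names = FALSE)
  write.csv(data.frame(id = seq_len(nrow(mesh$edges)),
                       node1 = mesh$edges[, 1], node2 = mesh$edges[, 2],
                       length = mesh$edge_length),
            file.path(dir, "edges.csv"), row.names = FALSE)
  write.csv(data.frame(id = seq_len(nrow(mesh$triangles)),
                       node1 = mesh$triangles[, 1],
                       node2 = mesh$triangles[, 2],
                       node3 = mesh$triangles[, 3],
                       area = mesh$tri_area),
            file.path(dir, "triangles.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write equilibrium tables as CSV
#'
#' `stretches.csv` (edge_id, lambda), `elements.csv` (tri_id, J, rho) and
#' `deformed_nodes.csv` (id, reference and deformed coordinates,
#' displacement, fixed flag).
#'
#' @param result an `equilibrium_result`.
#' @param dir output directory.
#' @export
write_result_csv <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mesh <- result$mesh
  write.csv(data.frame(edge_id = seq_along(result$stretch),
                       lambda = result$stretch),
            file.path(dir, "stretches.csv"), row.names = FALSE)
  write.csv(data.frame(tri_id = seq_along(result$jacobian),
                       J = result$jacobian, rho = result$densification),
            file.path(dir, "elements.csv"), row.names = FALSE)
  p <- result$config$positions
  write.csv(data.frame(id = seq_len(nrow(p)),
                       x_ref = mesh$nodes[, 1], y_ref = mesh$nodes[, 2],
                       x = p[, 1], y = p[, 2],
                       ux = p[, 1] - mesh$nodes[, 1],
                       uy = p[, 2] - mesh$nodes[, 2],
                       fixed = result$config$fixed),
            file.path(dir, "deformed_nodes.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write a metrics report as JSON
#'
#' @param report a [metrics_report()] (or any list of scalars).
#' @param path output path.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# full experiment output: mesh + result files, metrics, convergence log
write_experiment <- function(exp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mesh_csv(exp$mesh, dir)
  write_mesh_vtk(exp$mesh, file.path(dir, "mesh.vtk"))
  write_result_csv(exp$result, dir)
  write_result_vtk(exp$result, file.path(dir, "result.vtk"))
  write_metrics_json(exp$report, file.path(dir, "metrics.json"))
  if (!is.null(exp$sweep) && nrow(exp$sweep$diagnostics))
    write.csv(exp$sweep$diagnostics, file.path(dir, "convergence.csv"),
              row.names = FALSE)
  invisible(dir)
}

config_defaults <- list(
  experiment = "single_cell", law = "2-5", R = NULL, separation = 6,
  target_edge = NULL, seed = 1L, gamma = 0.5, gamma_step = 0.05,
  gamma_max = 0.8, gammas = NULL, R_values = c(5, 10),
  separations = c(4, 6), expansion = 0.5, Q = 50, b = 0.25,
  grad_tol = NULL, max_iter = 50000L, perturbation_amplitude = 1e-3,
  rho_threshold = 2, target_C = NULL)

#' Read and validate a run configuration
#'
#' Flat JSON with a fixed key set (unknown keys are rejected); missing keys
#' take the documented defaults. The fully resolved configuration is
#' attached to every run.
#'
#' @param path JSON file path.
#' @return a named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), names(config_defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(config_defaults, cfg)
  experiments <- c("single_cell", "single_cell_sweep", "decay_study",
                   "two_cell", "tether_phase_map", "low_connectivity",
                   "expansion", "size_effect")
  if (!cfg$experiment %in% experiments)
    stop("unknown experiment '", cfg$experiment, "'; expected one of: ",
         paste(experiments, collapse = ", "))
  structure(cfg, class = "run_config")
}

#' Run an experiment from a configuration
#'
#' @param cfg a [read_run_config()] result (or an equivalent list).
#' @param out_dir optional output directory for result files.
#' @return the experiment's return value (driver-dependent).
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  cfg <- modifyList(config_defaults, unclass(cfg))
  params <- penalty_params(cfg$Q, cfg$b)
  settings <- solver_settings(grad_tol = cfg$grad_tol,
                              max_iter = cfg$max_iter,
                              perturbation_amplitude =
                                cfg$perturbation_amplitude,
                              perturbation_seed = cfg$seed)
  edge_or <- function(default) cfg$target_edge %||% default
  out <- switch(cfg$experiment,
    single_cell = ,
    single_cell_sweep = run_single_cell(
      cfg$law, gamma = cfg$gamma, R = cfg$R %||% 10,
      target_edge = edge_or(0.25), seed = cfg$seed,
      gamma_step = cfg$gamma_step, params = params, settings = settings,
      rho_threshold = cfg$rho_threshold, out_dir = out_dir),
    decay_study = run_decay_study(
      cfg$law, gammas = cfg$gammas %||% cfg$gamma,
      R_values = cfg$R_values, target_edge = edge_or(0.3),
      seed = cfg$seed, gamma_step = cfg$gamma_step, params = params,
      settings = settings),
    two_cell = ,
    low_connectivity = run_two_cell(
      cfg$law, separation = cfg$separation, gamma = cfg$gamma,
      R = cfg$R %||% (cfg$separation / 2 + 5),
      target_edge = edge_or(0.25), seed = cfg$seed,
      gamma_step = cfg$gamma_step, params = params, settings = settings,
      rho_threshold = cfg$rho_threshold,
      target_C = if (cfg$experiment == "low_connectivity")
        cfg$target_C %||% 4.7 else cfg$target_C,
      out_dir = out_dir),
    tether_phase_map = run_tether_phase_map(
      cfg$law, separations = cfg$separations, gamma_max = cfg$gamma_max,
      gamma_step = cfg$gamma_step, target_edge = edge_or(0.4),
      seed = cfg$seed, params = params, settings = settings,
      rho_threshold = cfg$rho_threshold),
    expansion = run_expansion(
      cfg$law, expansion = cfg$expansion, R = cfg$R %||% 10,
      target_edge = edge_or(0.25), seed = cfg$seed,
      gamma_step = cfg$gamma_step, params = params, settings = settings,
      rho_threshold = cfg$rho_threshold),
    size_effect = {
      coarse <- run_single_cell(cfg$law, gamma = cfg$gamma,
                                R = cfg$R %||% 5, target_edge = 0.5,
                                seed = cfg$seed, gamma_step = cfg$gamma_step,
                                params = params, settings = settings,
                                rho_threshold = cfg$rho_threshold)
      fine <- run_single_cell(cfg$law, gamma = cfg$gamma,
                              R = cfg$R %||% 5,
                              target_edge = edge_or(0.2),
                              seed = cfg$seed, gamma_step = cfg$gamma_step,
                              params = params, settings = settings,
                              rho_threshold = cfg$rho_threshold)
      list(coarse = coarse, fine = fine,
           n_bands_coarse = sum(detect_bands(
             coarse$result, cfg$rho_threshold)$touching),
           n_bands_fine = sum(detect_bands(
             fine$result, cfg$rho_threshold)$touching))
    })
  attr(out, "config") <- cfg
  out
}
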