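#' @title Post-processing of equilibrium results
#' @description Densification ratios, stretch and orientation statistics,
#'   displacement decay-power fits, densified-band / tether detection and
#'   instability-onset detection.
#' @name metrics
NULL

# elements incident to a given cavity boundary (>= 1 node tagged on it)
elements_touching <- function(mesh, tag) {
  onb <- mesh$boundary == tag
  onb[mesh$triangles[, 1]] | onb[mesh$triangles[, 2]] |
    onb[mesh$triangles[, 3]]
}

elements_touching_any_cavity <- function(mesh) {
  out <- rep(FALSE, nrow(mesh$triangles))
  for (i in seq_len(nrow(mesh$cell_centers)))
    out <- out | elements_touching(mesh, paste0("cell_boundary_", i))
  out
}

#' Per-element densification ratios
#'
#' The densification ratio of a triangular element is `rho = 1 / J`, the
#' deformed-to-reference density ratio of a continuum deforming like the
#' element. An element with `J <= 0` in a converged result signals a
#' solver-quality failure (the penalty should prevent inversion) and raises
#' a warning.
#'
#' @param result an `equilibrium_result`.
#' @param exclude_cell_boundary drop elements touching a cavity boundary
#'   before taking the maximum.
#' @return list with per-element `rho`, `rho_max`, the element attaining it,
#'   and `J_min` (`= 1 / rho_max`).
#' @export
densification <- function(result, exclude_cell_boundary = FALSE) {
  J <- result$jacobian
  if (result$converged && any(J <= 0))
    warning(sprintf(
      "%d element(s) with J <= 0 in a converged result (solver failure)",
      sum(J <= 0)))
  rho <- 1 / J
  sel <- rep(TRUE, length(rho))
  if (exclude_cell_boundary)
    sel <- !elements_touching_any_cavity(result$mesh)
  imax <- which(sel)[which.max(rho[sel])]
  list(rho = rho, rho_max = rho[imax], element = imax,
       J_min = J[imax])
}

#' Minimum fiber stretch of an equilibrium
#'
#' @param result an `equilibrium_result`.
#' @param exclude_cell_boundary drop fibers lying on a cavity boundary
#'   (both endpoints on cavity-boundary nodes), as when isolating interior
#'   response from the prescribed boundary stretch `1 - gamma`.
#' @export
min_stretch <- function(result, exclude_cell_boundary = FALSE) {
  sel <- rep(TRUE, length(result$stretch))
  if (exclude_cell_boundary) sel <- !cavity_edge_mask(result$mesh)
  min(result$stretch[sel])
}

fiber_angles <- function(mesh, positions, reference, cell_center) {
  d <- positions[mesh$edges[, 1], , drop = FALSE] -
       positions[mesh$edges[, 2], , drop = FALSE]
  ang_fiber <- atan2(d[, 2], d[, 1])
  if (reference == "horizontal") {
    rel <- ang_fiber
  } else {
    mid <- (positions[mesh$edges[, 1], , drop = FALSE] +
            positions[mesh$edges[, 2], , drop = FALSE]) / 2
    ang_rad <- atan2(mid[, 2] - cell_center[2], mid[, 1] - cell_center[1])
    rel <- ang_fiber - ang_rad
  }
  # acute angle between undirected fiber and reference direction
  a <- abs(rel) %% pi
  a <- pmin(a, pi - a)
  a * 180 / pi
}

#' Tree-diagram table: stretch versus distance from the cell center
#'
#' One row per fiber: its stretch, the distance of its reference midpoint
#' from the cell center (in `r_c` units) and the acute angle between the
#' deformed fiber and the reference direction (radial through the fiber
#' midpoint, or horizontal for two-cell runs).
#'
#' @param result an `equilibrium_result`.
#' @param cell_center 2-vector; defaults to the first cell center.
#' @param reference `"radial"` or `"horizontal"`.
#' @return data frame with columns `edge`, `stretch`, `distance`, `angle`.
#' @export
stretch_tree <- function(result, cell_center = NULL,
                         reference = c("radial", "horizontal")) {
  reference <- match.arg(reference)
  mesh <- result$mesh
  if (is.null(cell_center)) cell_center <- mesh$cell_centers[1, ]
  mid <- (mesh$nodes[mesh$edges[, 1], , drop = FALSE] +
          mesh$nodes[mesh$edges[, 2], , drop = FALSE]) / 2
  dist <- sqrt((mid[, 1] - cell_center[1])^2 + (mid[, 2] - cell_center[2])^2)
  data.frame(
    edge = seq_len(nrow(mesh$edges)),
    stretch = result$stretch,
    distance = dist,
    angle = fiber_angles(mesh, result$config$positions, reference,
                         cell_center))
}

#' Power-law fit of the radial displacement decay
#'
#' Fits `|u_r| = A r^-n` by least squares on `log|u_r|` vs `log r` over the
#' free nodes whose reference radius lies in `fit_range` and whose inward
#' radial displacement magnitude exceeds `min_magnitude`. Two-dimensional
#' homogeneous linear elasticity gives `n = 1`; fibrous networks decay more
#' slowly (`n < 1`).
#'
#' @param result an `equilibrium_result`.
#' @param fit_range radial window `[r_lo, r_hi]` in `r_c` units (reference
#'   coordinates); default `c(1.2, 0.9 * R)` avoids both boundary layers.
#' @param cell_center 2-vector; defaults to the first cell center.
#' @param min_magnitude displacement floor below which nodes are ignored.
#' @param min_nodes minimum number of usable nodes.
#' @return list with `A`, `n` (positive decay power), `fit_range`,
#'   `n_nodes` and `residual` (residual standard error of the log-log fit).
#' @export
decay_fit <- function(result, fit_range = NULL, cell_center = NULL,
                      min_magnitude = 1e-8, min_nodes = 20) {
  mesh <- result$mesh
  if (is.null(cell_center)) cell_center <- mesh$cell_centers[1, ]
  if (is.null(fit_range)) fit_range <- c(1.2, 0.9 * mesh$R)
  ref <- mesh$nodes
  rx <- ref[, 1] - cell_center[1]
  ry <- ref[, 2] - cell_center[2]
  r <- sqrt(rx^2 + ry^2)
  u <- result$config$positions - ref
  ur <- (u[, 1] * rx + u[, 2] * ry) / r
  sel <- !result$config$fixed & r >= fit_range[1] & r <= fit_range[2] &
    ur < -min_magnitude
  if (sum(sel) < min_nodes)
    stop(sprintf("only %d usable nodes in the fit range (need >= %d)",
                 sum(sel), min_nodes))
  fit <- lm(log(-ur[sel]) ~ log(r[sel]))
  n <- -unname(coef(fit)[2])
  if (n <= 0)
    warning("fitted displacement field does not decay (n <= 0)")
  res <- stats::residuals(fit)
  list(A = exp(unname(coef(fit)[1])), n = n, fit_range = fit_range,
       n_nodes = sum(sel),
       residual = sqrt(sum(res^2) / max(1, fit$df.residual)))
}

# element adjacency graph restricted to `which_el`; returns list of
# components (integer vectors of element indices)
element_components <- function(mesh, which_el) {
  sel <- which(which_el)
  if (length(sel) == 0) return(list())
  em <- tri_edge_matrix(mesh$triangles[sel, , drop = FALSE])
  key <- paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]))
  owner <- rep(seq_along(sel), 3)
  pairs <- split(owner, key)
  pairs <- pairs[lengths(pairs) == 2]
  g <- igraph::make_empty_graph(n = length(sel), directed = FALSE)
  if (length(pairs))
    g <- igraph::add_edges(g, unlist(pairs, use.names = FALSE))
  comp <- igraph::components(g)$membership
  lapply(split(seq_along(sel), comp), function(i) sel[i])
}

#' Detect densified bands
#'
#' Connected components (edge adjacency of triangles) of elements with
#' `rho >= rho_threshold`. The reach of a component is the maximum distance
#' of any member element's deformed centroid from the (nearest) cell
#' center, expressed in deformed cell radii `(1 - gamma) r_c`; the global
#' band reach is the maximum over components touching a cavity boundary.
#'
#' @param result an `equilibrium_result`.
#' @param rho_threshold densification threshold (> 1); default 2 separates
#'   densified elements (`rho ~ 3` in unstable-family runs) from the
#'   background.
#' @return list with `components` (element index sets), `touching`
#'   (does the component reach a cavity boundary), `reach` per component,
#'   and the global `band_reach`.
#' @export
detect_bands <- function(result, rho_threshold = 2) {
  mesh <- result$mesh
  dense <- is.finite(result$jacobian) & result$jacobian > 0 &
    (1 / result$jacobian) >= rho_threshold
  comps <- element_components(mesh, dense)
  if (length(comps) == 0)
    return(list(components = list(), touching = logical(0),
                reach = numeric(0), band_reach = 0))
  pos <- result$config$positions
  cen_x <- (pos[mesh$triangles[, 1], 1] + pos[mesh$triangles[, 2], 1] +
            pos[mesh$triangles[, 3], 1]) / 3
  cen_y <- (pos[mesh$triangles[, 1], 2] + pos[mesh$triangles[, 2], 2] +
            pos[mesh$triangles[, 3], 2]) / 3
  gamma <- if (is.finite(result$gamma)) result$gamma else 0
  r_def <- (1 - gamma) * mesh$cell_radius
  dmin <- rep(Inf, nrow(mesh$triangles))
  for (i in seq_len(nrow(mesh$cell_centers)))
    dmin <- pmin(dmin, sqrt((cen_x - mesh$cell_centers[i, 1])^2 +
                            (cen_y - mesh$cell_centers[i, 2])^2))
  touch_any <- elements_touching_any_cavity(mesh)
  touching <- vapply(comps, function(el) any(touch_any[el]), TRUE)
  reach <- vapply(comps, function(el) max(dmin[el]) / r_def, 0)
  band_reach <- if (any(touching)) max(reach[touching]) else 0
  list(components = comps, touching = touching, reach = reach,
       band_reach = band_reach)
}

#' Detect an intercellular tether
#'
#' A solid tether is an unbroken densified path joining the two cells: a
#' single connected component of elements with `rho >= rho_threshold` that
#' contains at least one element incident to EACH cavity boundary.
#'
#' @param result an `equilibrium_result` on a two-cell mesh.
#' @param rho_threshold densification threshold (default 2).
#' @return list with logical `tether` and the `elements` of the tether
#'   component (empty if none).
#' @export
detect_tether <- function(result, rho_threshold = 2) {
  mesh <- result$mesh
  if (nrow(mesh$cell_centers) < 2)
    stop("detect_tether requires a two-cell mesh")
  dense <- is.finite(result$jacobian) & result$jacobian > 0 &
    (1 / result$jacobian) >= rho_threshold
  comps <- element_components(mesh, dense)
  t1 <- elements_touching(mesh, "cell_boundary_1")
  t2 <- elements_touching(mesh, "cell_boundary_2")
  for (el in comps)
    if (any(t1[el]) && any(t2[el]))
      return(list(tether = TRUE, elements = el))
  list(tether = FALSE, elements = integer(0))
}

#' Detect instability onsets along a contraction sweep
#'
#' Fiber-collapse onset: first level whose minimum fiber stretch departs
#' from the boundary-imposed line `lambda_min = 1 - gamma` by more than
#' `delta`. Element-collapse onset: first level where `1 / rho_max`
#' (`= J_min`) drops by more than a factor `drop_factor` between
#' consecutive levels. Either may be absent (`NA`).
#'
#' @param sweep a `sweep_result` with at least 3 levels.
#' @param delta departure tolerance in stretch units (default 0.1, large
#'   enough to clear mesh noise but far below the collapse drop).
#' @param drop_factor consecutive-level drop factor (default 1.5).
#' @return list with `fiber_collapse` and `element_collapse` onset
#'   contraction levels (or `NA_real_`).
#' @export
onset_detection <- function(sweep, delta = 0.1, drop_factor = 1.5) {
  d <- sweep$diagnostics
  if (nrow(d) < 3) stop("onset detection needs a sweep with >= 3 levels")
  fib <- which(d$lambda_min < (1 - d$gamma) - delta)
  el <- which(d$J_min[-1] < d$J_min[-nrow(d)] / drop_factor) + 1L
  list(fiber_collapse = if (length(fib)) d$gamma[min(fib)] else NA_real_,
       element_collapse = if (length(el)) d$gamma[min(el)] else NA_real_)
}

#' Orientation histogram of fibers in a region
#'
#' Acute angles (degrees, `[0, 90]`) between deformed fibers and a
#' reference direction, binned in `bin_width`-degree bins and split by
#' tension (`lambda > 1`) versus compression (`lambda < 1`).
#'
#' @param result an `equilibrium_result`.
#' @param region element indices defining the region (fibers belonging to
#'   those elements are used); `NULL` means all fibers.
#' @param reference `"radial"` (angle to the ray from the cell center
#'   through the fiber midpoint) or `"horizontal"` (the two-cell axis).
#' @param cell_center 2-vector; defaults to the first cell center.
#' @param bin_width bin width in degrees (default 10).
#' @return data frame with `bin_lo`, `bin_hi`, `tension`, `compression`
#'   counts.
#' @export
orientation_histogram <- function(result, region = NULL,
                                  reference = c("radial", "horizontal"),
                                  cell_center = NULL, bin_width = 10) {
  reference <- match.arg(reference)
  mesh <- result$mesh
  if (is.null(cell_center)) {
    cell_center <- if (nrow(mesh$cell_centers)) mesh$cell_centers[1, ]
                   else c(0, 0)
  }
  if (is.null(region)) {
    edge_sel <- rep(TRUE, nrow(mesh$edges))
  } else {
    if (length(region) == 0) stop("region must be non-empty")
    em <- tri_edge_matrix(mesh$triangles[region, , drop = FALSE])
    key <- paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]))
    ekey <- paste(mesh$edges[, 1], mesh$edges[, 2])
    edge_sel <- ekey %in% key
  }
  ang <- fiber_angles(mesh, result$config$positions, reference,
                      cell_center)[edge_sel]
  lam <- result$stretch[edge_sel]
  breaks <- seq(0, 90, by = bin_width)
  bin <- cut(pmin(ang, 90 - 1e-9), breaks, right = FALSE)
  data.frame(
    bin_lo = breaks[-length(breaks)],
    bin_hi = breaks[-1],
    tension = as.vector(table(bin[lam > 1])),
    compression = as.vector(table(bin[lam < 1])))
}

#' Summary metrics report for an equilibrium
#'
#' Convenience bundle of the individual metrics: extreme stretches and
#' densification (with and without cavity-boundary exclusion), densified
#' bands, and the tether verdict for two-cell meshes.
#'
#' @param result an `equilibrium_result`.
#' @param rho_threshold band/tether densification threshold.
#' @export
metrics_report <- function(result, rho_threshold = 2) {
  mesh <- result$mesh
  dens <- densification(result)
  bands <- detect_bands(result, rho_threshold)
  rep <- list(
    gamma = result$gamma,
    law = result$law$label,
    energy = result$energy,
    converged = result$converged,
    lambda_min = min_stretch(result, exclude_cell_boundary = FALSE),
    lambda_min_interior = min_stretch(result, exclude_cell_boundary = TRUE),
    lambda_max = max(result$stretch),
    rho_max = dens$rho_max,
    rho_max_interior =
      densification(result, exclude_cell_boundary = TRUE)$rho_max,
    J_min = min(result$jacobian),
    n_inverted = sum(result$jacobian <= 0),
    n_bands = length(bands$components),
    band_reach = bands$band_reach,
    rho_threshold = rho_threshold)
  if (nrow(mesh$cell_centers) >= 2) {
    tet <- detect_tether(result, rho_threshold)
    rep$tether <- tet$tether
    rep$tether_elements <- length(tet$elements)
  }
  rep
}
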