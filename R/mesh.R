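#' @title Triangulated annular fiber-network domains
#' @description
#' The matrix domain is a disk of radius `R` (in units of the cell radius
#' `r_c = 1`) with one or two circular cavities of radius 1 representing
#' cells. The network is built from boundary rings discretized at arc
#' spacing ~ `target_edge` plus interior points on a seeded, jittered
#' hexagonal lattice, triangulated by Delaunay; triangles falling inside a
#' cavity are discarded. Every triangle side is a fiber.
#' @name domain_mesh
NULL

# run expr with a private RNG stream from `seed`, restoring the user's RNG
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

ring_points <- function(center, radius, target_edge, phase) {
  n <- round(2 * pi * radius / target_edge)
  theta <- 2 * pi * (seq_len(n) - 1) / n + phase
  # tiny deterministic radial perturbation (~1e-10 r_c) breaks the exact
  # cocircularity that would otherwise make the Delaunay test degenerate
  r <- radius * (1 + 2e-10 * cos(3 * theta + 1))
  list(xy = cbind(center[1] + r * cos(theta), center[2] + r * sin(theta)),
       n = n)
}

signed_area2 <- function(nodes, tri) {
  a <- nodes[tri[, 1], , drop = FALSE]
  b <- nodes[tri[, 2], , drop = FALSE]
  c <- nodes[tri[, 3], , drop = FALSE]
  (b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) -
    (b[, 2] - a[, 2]) * (c[, 1] - a[, 1])
}

tri_edge_matrix <- function(tri) {
  rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
}

drop_cavity_triangles <- function(tri, pts, centers) {
  cen_x <- (pts[tri[, 1], 1] + pts[tri[, 2], 1] + pts[tri[, 3], 1]) / 3
  cen_y <- (pts[tri[, 1], 2] + pts[tri[, 2], 2] + pts[tri[, 3], 2]) / 3
  drop <- rep(FALSE, nrow(tri))
  for (i in seq_len(nrow(centers)))
    drop <- drop |
      sqrt((cen_x - centers[i, 1])^2 + (cen_y - centers[i, 2])^2) < 1
  tri[!drop, , drop = FALSE]
}

build_annulus_mesh <- function(R, centers, target_edge, seed, n_smooth = 2L,
                               jitter = 0.25) {
  stopifnot(R > 1, target_edge > 0, target_edge < 1)
  n_cells <- nrow(centers)

  pts <- NULL
  tags <- character(0)
  for (i in seq_len(n_cells)) {
    ring <- ring_points(centers[i, ], 1, target_edge, phase = 0.1 * i)
    if (ring$n < 8)
      stop("infeasible resolution: fewer than 8 nodes on a cavity boundary")
    pts <- rbind(pts, ring$xy)
    tags <- c(tags, rep(paste0("cell_boundary_", i), ring$n))
  }
  outer <- ring_points(c(0, 0), R, target_edge, phase = 0.05)
  pts <- rbind(pts, outer$xy)
  tags <- c(tags, rep("outer_boundary", outer$n))

  # jittered hexagonal lattice in the interior, clear of both boundaries
  a <- target_edge
  h <- a * sqrt(3) / 2
  jmax <- ceiling(R / h)
  imax <- ceiling(R / a) + 1
  grid <- expand.grid(i = -imax:imax, j = -jmax:jmax)
  gx <- grid$i * a + (grid$j %% 2) * a / 2
  gy <- grid$j * h
  jit <- with_seed(seed, {
    cbind(runif(length(gx), -jitter * a, jitter * a),
          runif(length(gx), -jitter * a, jitter * a))
  })
  gx <- gx + jit[, 1]
  gy <- gy + jit[, 2]
  keep <- sqrt(gx^2 + gy^2) <= R - 0.55 * a
  for (i in seq_len(n_cells))
    keep <- keep &
      sqrt((gx - centers[i, 1])^2 + (gy - centers[i, 2])^2) >= 1 + 0.55 * a
  pts <- rbind(pts, cbind(gx[keep], gy[keep]))
  tags <- c(tags, rep("interior", sum(keep)))

  # a few Laplacian smoothing passes (boundary nodes pinned) relax the
  # jittered lattice into a well-shaped quasi-uniform triangulation while
  # keeping it unstructured
  interior <- tags == "interior"
  for (pass in seq_len(n_smooth)) {
    tri <- .delaunay_cpp(pts)
    tri <- drop_cavity_triangles(tri, pts, centers)
    idx <- c(tri[, 1], tri[, 2], tri[, 3], tri[, 2], tri[, 3], tri[, 1])
    nbr <- c(tri[, 2], tri[, 3], tri[, 1], tri[, 1], tri[, 2], tri[, 3])
    sx <- numeric(nrow(pts)); sy <- numeric(nrow(pts))
    acc_x <- rowsum(pts[nbr, 1], idx)
    acc_y <- rowsum(pts[nbr, 2], idx)
    rows <- as.integer(rownames(acc_x))
    sx[rows] <- acc_x; sy[rows] <- acc_y
    cnt <- tabulate(idx, nbins = nrow(pts))
    upd <- interior & cnt > 0
    pts[upd, 1] <- sx[upd] / cnt[upd]
    pts[upd, 2] <- sy[upd] / cnt[upd]
    # keep smoothed nodes clear of both boundaries
    for (i in seq_len(n_cells)) {
      dx <- pts[, 1] - centers[i, 1]
      dy <- pts[, 2] - centers[i, 2]
      r <- sqrt(dx^2 + dy^2)
      bad <- interior & r < 1 + 0.4 * a
      if (any(bad)) {
        f <- (1 + 0.4 * a) / r[bad]
        pts[bad, 1] <- centers[i, 1] + dx[bad] * f
        pts[bad, 2] <- centers[i, 2] + dy[bad] * f
      }
    }
    r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
    bad <- interior & r > R - 0.4 * a
    if (any(bad)) {
      f <- (R - 0.4 * a) / r[bad]
      pts[bad, ] <- pts[bad, , drop = FALSE] * f
    }
  }

  tri <- .delaunay_cpp(pts)
  # drop triangles inside a cavity (centroid test; cavities are convex)
  tri <- drop_cavity_triangles(tri, pts, centers)

  # enforce CCW orientation, drop degenerate slivers
  s2 <- signed_area2(pts, tri)
  flip <- s2 < 0
  tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]
  s2 <- abs(s2)
  ok <- s2 > 1e-12 * a^2
  tri <- tri[ok, , drop = FALSE]
  s2 <- s2[ok]

  used <- sort(unique(as.vector(tri)))
  if (length(used) < nrow(pts)) {
    remap <- integer(nrow(pts))
    remap[used] <- seq_along(used)
    tri <- matrix(remap[tri], ncol = 3)
    pts <- pts[used, , drop = FALSE]
    tags <- tags[used]
  }

  em <- tri_edge_matrix(tri)
  em <- cbind(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]))
  edges <- unique(em)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  el <- sqrt(rowSums((pts[edges[, 1], , drop = FALSE] -
                      pts[edges[, 2], , drop = FALSE])^2))

  mesh <- structure(
    list(nodes = pts,
         edges = edges,
         edge_length = el,
         triangles = tri,
         tri_area = s2 / 2,
         boundary = tags,
         cell_centers = centers,
         cell_radius = 1,
         R = R,
         target_edge = target_edge,
         seed = seed),
    class = "fiber_mesh")
  mesh
}

#' Build a single-cell annular mesh
#'
#' @param R outer domain radius, in units of the cell radius `r_c` (`R > 1`).
#' @param target_edge target fiber length in units of `r_c`
#'   (`0 < target_edge < 1`).
#' @param seed integer seed controlling the lattice jitter; the mesh is a
#'   deterministic function of `(R, target_edge, seed)`.
#' @return a `fiber_mesh`: node coordinates, fiber edges with reference
#'   lengths, CCW triangles with reference areas, per-node boundary tags
#'   (`interior`, `cell_boundary_1`, `cell_boundary_2`, `outer_boundary`),
#'   cell centers and domain radii.
#' @examples
#' m <- build_single_cell_mesh(R = 4, target_edge = 0.4, seed = 1)
#' mean_coordination(m)
#' @export
build_single_cell_mesh <- function(R, target_edge, seed = 1L) {
  build_annulus_mesh(R, matrix(c(0, 0), 1, 2), target_edge, seed)
}

#' Build a two-cell annular mesh
#'
#' Two unit-radius cavities placed symmetrically about the origin along the
#' x axis, center-to-center distance `separation`.
#'
#' @inheritParams build_single_cell_mesh
#' @param separation center-to-center cavity distance in `r_c` units; must
#'   exceed 2 (non-overlapping) and leave >= 1 `r_c` clearance to the outer
#'   boundary.
#' @export
build_two_cell_mesh <- function(R, separation, target_edge, seed = 1L) {
  if (separation <= 2)
    stop("cavities overlap: separation must exceed 2 cell radii")
  if (separation / 2 + 1 + 1 > R)
    stop("cavities must clear the outer boundary by at least 1 cell radius")
  centers <- matrix(c(-separation / 2, 0, separation / 2, 0),
                    2, 2, byrow = TRUE)
  build_annulus_mesh(R, centers, target_edge, seed)
}

#' Mean nodal coordination (connectivity) of a mesh
#'
#' @param mesh a `fiber_mesh`.
#' @param which `"all"` for 2E/N over all nodes, `"interior"` for the mean
#'   degree of interior-tagged nodes only.
#' @export
mean_coordination <- function(mesh, which = c("all", "interior")) {
  which <- match.arg(which)
  deg <- tabulate(as.vector(mesh$edges), nbins = nrow(mesh$nodes))
  if (which == "all") mean(deg) else mean(deg[mesh$boundary == "interior"])
}

# edges whose both endpoints sit on a cavity boundary ("on the cell boundary")
cavity_edge_mask <- function(mesh) {
  onb <- startsWith(mesh$boundary, "cell_boundary")
  onb[mesh$edges[, 1]] & onb[mesh$edges[, 2]]
}

#' Randomly remove fibers to lower the network connectivity
#'
#' Edges are removed uniformly at random until the mean coordination 2E/N is
#' within 0.1 of `target_C`. Cavity-boundary fibers are never removed, and a
#' removal that would disconnect the network is never performed. Triangles
#' that lose a side keep their area-penalty term by default: the penalty
#' models excluded volume of matter, not any specific fiber.
#'
#' @param mesh a `fiber_mesh`.
#' @param target_C target mean coordination, `3 <= target_C <=` current mean.
#' @param seed integer seed for the removal order.
#' @param retain_penalty keep the area penalty of triangles with a removed
#'   side (default `TRUE`); if `FALSE` such triangles are dropped entirely.
#' @return the reduced `fiber_mesh`.
#' @export
reduce_connectivity <- function(mesh, target_C, seed = 1L,
                                retain_penalty = TRUE) {
  N <- nrow(mesh$nodes)
  C_now <- 2 * nrow(mesh$edges) / N
  if (target_C < 3 || target_C > C_now + 1e-9)
    stop("target_C must lie in [3, current mean coordination]")
  edges <- mesh$edges
  protected <- cavity_edge_mask(mesh)
  keep <- rep(TRUE, nrow(edges))

  with_seed(seed, {
    repeat {
      C_cur <- 2 * sum(keep) / N
      if (C_cur <= target_C + 0.1) break
      g <- igraph::graph_from_edgelist(edges[keep, , drop = FALSE],
                                       directed = FALSE)
      if (igraph::vcount(g) < N)
        g <- igraph::add_vertices(g, N - igraph::vcount(g))
      bridge_rows <- which(keep)[igraph::bridges(g)]
      cand <- which(keep & !protected)
      cand <- setdiff(cand, bridge_rows)
      if (length(cand) == 0)
        stop("cannot reach target connectivity without disconnecting ",
             "the network")
      keep[cand[sample.int(length(cand), 1)]] <- FALSE
    }
  })

  mesh$edges <- edges[keep, , drop = FALSE]
  mesh$edge_length <- mesh$edge_length[keep]
  if (!retain_penalty) {
    ek <- paste(mesh$edges[, 1], mesh$edges[, 2])
    em <- tri_edge_matrix(mesh$triangles)
    em <- paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]))
    present <- matrix(em %in% ek, ncol = 3)
    full <- rowSums(present) == 3L
    mesh$triangles <- mesh$triangles[full, , drop = FALSE]
    mesh$tri_area <- mesh$tri_area[full]
  }
  mesh$removed_edges <- sum(!keep)
  mesh
}

#' @export
print.fiber_mesh <- function(x, ...) {
  cat(sprintf(paste0(
    "<fiber_mesh> %d nodes, %d fibers, %d triangles\n",
    "  R = %g r_c, %d cell(s), target edge %g r_c, seed %d\n",
    "  mean coordination %.2f (interior %.2f)\n"),
    nrow(x$nodes), nrow(x$edges), nrow(x$triangles),
    x$R, nrow(x$cell_centers), x$target_edge, x$seed,
    mean_coordination(x), mean_coordination(x, "interior")))
  invisible(x)
}
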