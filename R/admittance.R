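#' Branch conductance between two adjacent voxels
#'
#' Two half-voxel resistors in series through the shared face: face area
#' `h^2`, total length `h`, so `G = 2 h / (rho_i + rho_j)` siemens.
#'
#' @param rho_i,rho_j voxel resistivities (ohm m).
#' @param h voxel edge (m).
#' @export
branch_conductance <- function(rho_i, rho_j, h) 2 * h / (rho_i + rho_j)

#' Assemble the admittance (resistor-network) system of a voxel grid
#'
#' One electrical node per voxel (the computational cell), 6-connected.
#' Faces on the domain boundary are open circuits, i.e. the boundary is
#' insulating. The assembled operator is the weighted graph Laplacian
#' `L = D - W` with face conductances from [branch_conductance()]; labels
#' enter only through the resistivity table.
#'
#' @param grid a [voxel_grid()].
#' @return An `admittance_system`: the sparse Laplacian plus grid metadata.
#' @export
assemble_network <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- grid$dims
  h <- grid$spacing
  n <- prod(d)
  rho <- as.numeric(grid_resistivity(grid))

  ii <- integer(0); jj <- integer(0); gg <- numeric(0)
  deg <- numeric(n)
  strides <- c(1L, d[1L], d[1L] * d[2L])
  for (ax in 1:3) {
    ijk_ax <- switch(ax,
      (seq_len(n) - 1L) %% d[1L],
      ((seq_len(n) - 1L) %/% d[1L]) %% d[2L],
      (seq_len(n) - 1L) %/% (d[1L] * d[2L]))
    a <- which(ijk_ax < d[ax] - 1L)
    b <- a + strides[ax]
    g <- branch_conductance(rho[a], rho[b], h)
    ii <- c(ii, a); jj <- c(jj, b); gg <- c(gg, g)
    deg[a] <- deg[a] + g
    deg[b] <- deg[b] + g
  }
  L <- Matrix::sparseMatrix(i = c(ii, jj, seq_len(n)),
                            j = c(jj, ii, seq_len(n)),
                            x = c(-gg, -gg, deg),
                            dims = c(n, n), repr = "C")
  structure(list(n = n, L = L, dims = d, spacing = h,
                 origin = grid$origin),
            class = "admittance_system")
}

#' @method print admittance_system
#' @export
print.admittance_system <- function(x, ...) {
  cat("<admittance_system> ", x$n, " nodes, ",
      length(x$L@x), " stored entries\n", sep = "")
  invisible(x)
}

#' Solve the network for node potentials under unit current injection
#'
#' Injects +1 A split equally over `sources` and -1 A over `sinks`, grounds
#' the reference node (the sink node nearest the sink-set centroid by
#' default) and solves the nodal equations. Large systems use conjugate
#' gradients with a shifted incomplete-Cholesky preconditioner; systems
#' below `direct_limit` nodes may use a dense direct solve (the oracle path
#' for reciprocity tests).
#'
#' @param system an [assemble_network()] result.
#' @param sources,sinks disjoint, non-empty vectors of node indices.
#' @param tol relative residual tolerance.
#' @param maxit iteration cap for the conjugate-gradient solve.
#' @param method `"auto"`, `"pcg"` or `"direct"`.
#' @param reference node to ground; default sink centroid node.
#' @param direct_limit largest n for which `"auto"` picks the dense solve.
#' @return A `field_solution` holding node potentials in volts per ampere.
#' @export
solve_unit_field <- function(system, sources, sinks, tol = 1e-8,
                             maxit = 20000L,
                             method = c("auto", "pcg", "direct"),
                             reference = NULL, direct_limit = 4000L) {
  method <- match.arg(method)
  sources <- as.integer(sources); sinks <- as.integer(sinks)
  if (!length(sources) || !length(sinks))
    stop("sources and sinks must be non-empty")
  if (length(intersect(sources, sinks)))
    stop("sources and sinks must be disjoint")
  n <- system$n
  if (any(c(sources, sinks) < 1L) || any(c(sources, sinks) > n))
    stop("electrode node index out of range")

  b <- numeric(n)
  b[sources] <- b[sources] + 1 / length(sources)
  b[sinks] <- b[sinks] - 1 / length(sinks)

  if (is.null(reference)) {
    cen <- colMeans(node_ijk(system$dims, sinks))
    dd <- rowSums(sweep(node_ijk(system$dims, sinks), 2L, cen, "-")^2)
    reference <- sinks[which.min(dd)]
  }
  reference <- as.integer(reference)

  if (method == "auto") method <- if (n <= direct_limit) "direct" else "pcg"

  if (method == "direct") {
    Ld <- as.matrix(system$L)
    Ld[reference, ] <- 0; Ld[, reference] <- 0; Ld[reference, reference] <- 1
    bb <- b; bb[reference] <- 0
    v <- solve(Ld, bb)
    res <- sqrt(sum((Ld %*% v - bb)^2)) / sqrt(sum(bb^2))
    iters <- NA_integer_
  } else {
    Lc <- system$L
    out <- .pcg_solve(Lc@p, Lc@i, Lc@x, b, reference - 1L, tol,
                      as.integer(maxit))
    v <- out$x
    res <- out$relres
    iters <- out$iterations
    if (res > tol)
      stop(sprintf(
        "admittance solve did not converge: relative residual %.3g after %d iterations",
        res, iters))
  }
  structure(list(potentials = as.numeric(v), sources = sources,
                 sinks = sinks, reference = reference, residual = res,
                 iterations = iters, method = method,
                 dims = system$dims, spacing = system$spacing,
                 origin = system$origin),
            class = "field_solution")
}

#' @method print field_solution
#' @export
print.field_solution <- function(x, ...) {
  cat("<field_solution> ", length(x$potentials), " nodes, residual ",
      format(x$residual, digits = 3), " (", x$method, ")\n", sep = "")
  invisible(x)
}

#' Kirchhoff residual of a field solution
#'
#' Maximum absolute net branch current out of any non-electrode,
#' non-reference node, relative to the injected current (1 A).
#'
#' @param system the [assemble_network()] system the solution came from.
#' @param solution a [solve_unit_field()] result.
#' @export
kirchhoff_residual <- function(system, solution) {
  b <- numeric(system$n)
  b[solution$sources] <- 1 / length(solution$sources)
  b[solution$sinks] <- b[solution$sinks] - 1 / length(solution$sinks)
  r <- as.numeric(system$L %*% solution$potentials) - b
  skip <- c(solution$sources, solution$sinks, solution$reference)
  max(abs(r[-skip]))
}

#' Interpolate node potentials at arbitrary points
#'
#' Trilinear interpolation over the voxel-centre lattice. Exact at nodes
#' and exact for fields linear in position.
#'
#' @param solution a [solve_unit_field()] result.
#' @param grid the originating [voxel_grid()].
#' @param points numeric matrix (n x 3) of positions in metres.
#' @return Potentials in volts per ampere at the points.
#' @export
potential_at <- function(solution, grid, points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  d <- solution$dims
  h <- solution$spacing
  org <- solution$origin + h / 2  # centre-lattice origin
  u <- sweep(points, 2L, org, "-") / h
  i0 <- floor(u)
  frac <- u - i0
  # points exactly on the last centre plane belong to the last cell
  at_top <- i0 == matrix(rep(d - 1L, each = nrow(u)), ncol = 3L) & frac == 0
  i0[at_top] <- i0[at_top] - 1
  frac[at_top] <- 1
  bad <- which(i0[, 1L] < 0 | i0[, 2L] < 0 | i0[, 3L] < 0 |
                 i0[, 1L] > d[1L] - 2L | i0[, 2L] > d[2L] - 2L |
                 i0[, 3L] > d[3L] - 2L)
  if (length(bad))
    stop("point out of interpolation bounds: (",
         paste(signif(points[bad[1L], ], 6), collapse = ", "), ") m")
  storage.mode(i0) <- "integer"
  v <- solution$potentials
  val <- numeric(nrow(points))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    idx <- node_index(d, cbind(i0[, 1L] + cx, i0[, 2L] + cy, i0[, 3L] + cz))
    w <- (if (cx == 1) frac[, 1L] else 1 - frac[, 1L]) *
      (if (cy == 1) frac[, 2L] else 1 - frac[, 2L]) *
      (if (cz == 1) frac[, 3L] else 1 - frac[, 3L])
    val <- val + w * v[idx]
  }
  val
}

#' Analytic point-source potential in an infinite homogeneous medium
#'
#' `V = rho * I / (4 pi r)`. Test oracle for the discrete solver.
#'
#' @param rho resistivity (ohm m).
#' @param current injected current (A).
#' @param r distance from the source (m), `> 0`.
#' @return Potential in volts.
#' @export
analytic_point_source <- function(rho, current, r) {
  if (any(r <= 0)) stop("r must be > 0")
  rho * current / (4 * pi * r)
}

#' Export a field solution as CSV (node positions and V per A)
#'
#' @param solution a [solve_unit_field()] result.
#' @param grid the originating grid.
#' @param path output CSV path.
#' @export
write_field <- function(solution, grid, path) {
  pos <- node_position(grid, seq_along(solution$potentials))
  df <- data.frame(x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
                   v_per_A = solution$potentials)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
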