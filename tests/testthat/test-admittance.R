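test_that("branch conductance follows the half-voxel series formula", {
  # two adjacent vitreous voxels at 0.2 mm spacing
  expect_equal(branch_conductance(0.666, 0.666, 0.2e-3),
               2 * 2e-4 / (2 * 0.666), tolerance = 1e-12)
  expect_equal(branch_conductance(0.666, 0.666, 0.2e-3), 3.003e-4,
               tolerance = 1e-3)
  # doubling every resistivity halves every branch conductance
  g <- uniform_grid(c(5, 5, 5), 0.1e-3, rho = 1)
  g2 <- uniform_grid(c(5, 5, 5), 0.1e-3, rho = 2)
  expect_equal(assemble_network(g)$L@x, 2 * assemble_network(g2)$L@x)
})

test_that("the analytic point source behaves as rho*I/(4 pi r)", {
  expect_equal(analytic_point_source(0.666, 1e-4, 1e-3), 5.30e-3,
               tolerance = 1e-3)
  expect_equal(analytic_point_source(1, 1, 2), analytic_point_source(1, 1, 1) / 2)
  expect_identical(analytic_point_source(1, 0, 1), 0)
  expect_error(analytic_point_source(1, 1, 0), "r must be")
})

solve_point_source <- function(dims, h, method = "pcg") {
  g <- uniform_grid(dims, h)
  sys <- assemble_network(g)
  d <- g$dims
  ijk <- retistim:::node_ijk(d, seq_len(prod(d)))
  src <- retistim:::node_index(d, matrix(floor(d / 2), 1))
  bnd <- which(ijk[, 1] == 0 | ijk[, 2] == 0 | ijk[, 3] == 0 |
                 ijk[, 1] == d[1] - 1 | ijk[, 2] == d[2] - 1 |
                 ijk[, 3] == d[3] - 1)
  sol <- solve_unit_field(sys, src, bnd, method = method)
  list(grid = g, sys = sys, sol = sol,
       centre = voxel_centre(g, matrix(floor(d / 2), 1)))
}

test_that("homogeneous-medium solve matches the point-source oracle within 5%", {
  ps <- solve_point_source(c(41, 41, 41), 0.25e-3)
  h <- 0.25e-3
  rho <- 0.666
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 1) / sqrt(3), c(1, -1, 0) / sqrt(2))
  rs <- seq(3 * h, 10 * h, by = h)  # 3h .. domain/4
  # fix the additive gauge at the outermost probe shell (the closed form
  # is referenced at infinity, the discrete solution at the sink set)
  rmax <- max(rs)
  anchor <- sweep(dirs * rmax, 2L, ps$centre, "+")
  offset <- mean(analytic_point_source(rho, 1, rmax) -
                   potential_at(ps$sol, ps$grid, anchor))
  for (r in rs) {
    pts <- sweep(dirs * r, 2L, ps$centre, "+")
    v <- potential_at(ps$sol, ps$grid, pts) + offset
    expect_lt(max(abs(v - analytic_point_source(rho, 1, r))) /
                analytic_point_source(rho, 1, r), 0.05)
  }
  # scaled to the printed example: 100 uA at 1 mm in vitreous ~ 5.30 mV
  pts <- sweep(dirs * 1e-3, 2L, ps$centre, "+")
  v_mV <- (mean(potential_at(ps$sol, ps$grid, pts)) + offset) * 100e-6 * 1e3
  expect_equal(v_mV, 5.30, tolerance = 0.05)
})

test_that("Kirchhoff's current law holds at non-electrode nodes", {
  ps <- solve_point_source(c(15, 15, 15), 0.5e-3, method = "direct")
  expect_lt(kirchhoff_residual(ps$sys, ps$sol), 1e-8)
  ps2 <- solve_point_source(c(25, 25, 25), 0.4e-3, method = "pcg")
  expect_lt(kirchhoff_residual(ps2$sys, ps2$sol), 1e-8)
})

test_that("swapping sources and sinks negates the potentials", {
  g <- uniform_grid(c(8, 8, 8), 0.5e-3)
  sys <- assemble_network(g)
  a <- retistim:::node_index(g$dims, matrix(c(2, 2, 2), 1))
  b <- retistim:::node_index(g$dims, matrix(c(5, 5, 5), 1))
  ref <- b
  s1 <- solve_unit_field(sys, a, b, reference = ref, method = "direct")
  s2 <- solve_unit_field(sys, b, a, reference = ref, method = "direct")
  expect_equal(s1$potentials, -s2$potentials, tolerance = 1e-10)
})

test_that("reciprocity holds against the dense oracle on small grids", {
  # with the sink at a common reference node c (grounded), reciprocity of
  # the symmetric network reads V_a(b) = V_b(a), both referenced at c
  g <- uniform_grid(c(9, 9, 9), 0.5e-3)  # 729 nodes
  sys <- assemble_network(g)
  d <- g$dims
  sink <- retistim:::node_index(d, matrix(c(0, 0, 0), 1))
  a <- retistim:::node_index(d, matrix(c(2, 3, 5), 1))
  b <- retistim:::node_index(d, matrix(c(6, 5, 7), 1))
  va <- solve_unit_field(sys, a, sink, method = "direct")
  vb <- solve_unit_field(sys, b, sink, method = "direct")
  expect_equal(va$potentials[b], vb$potentials[a], tolerance = 1e-9)
  # and the iterative path agrees with the dense oracle
  va_it <- solve_unit_field(sys, a, sink, method = "pcg", tol = 1e-10)
  expect_equal(va_it$potentials, va$potentials, tolerance = 1e-6)
})

test_that("trilinear interpolation is exact at nodes and on linear fields", {
  g <- uniform_grid(c(6, 5, 4), 0.3e-3)
  n <- prod(g$dims)
  pos <- node_position(g, seq_len(n))
  lin <- 2.5 * pos[, 1] - 1.25 * pos[, 2] + 0.75 * pos[, 3] + 0.1
  sol <- structure(list(potentials = lin, dims = g$dims, spacing = g$spacing,
                        origin = g$origin), class = "field_solution")
  # node identity
  idx <- c(1L, 17L, n %/% 2L, n)
  expect_equal(potential_at(sol, g, pos[idx, ]), lin[idx], tolerance = 1e-12)
  # cell centre = mean of 8 corner values (true for any node field)
  sol2 <- sol
  set.seed(42)
  sol2$potentials <- rnorm(n)
  corner <- retistim:::node_ijk(g$dims, seq_len(n))
  cc <- voxel_centre(g, matrix(c(2, 2, 1), 1)) + g$spacing / 2
  eight <- expand.grid(0:1, 0:1, 0:1)
  vals <- sol2$potentials[retistim:::node_index(
    g$dims, as.matrix(sweep(eight, 2L, c(2, 2, 1), "+")))]
  expect_equal(as.numeric(potential_at(sol2, g, cc)), mean(vals),
               tolerance = 1e-12)
  # linear fields are reproduced anywhere in the interior
  set.seed(1)
  pts <- cbind(runif(25, 4e-4, 1.2e-3), runif(25, 4e-4, 1e-3),
               runif(25, 4e-4, 8e-4))
  expect_equal(potential_at(sol, g, pts),
               2.5 * pts[, 1] - 1.25 * pts[, 2] + 0.75 * pts[, 3] + 0.1,
               tolerance = 1e-12)
  # out-of-bounds points are named in the error
  expect_error(potential_at(sol, g, matrix(c(9, 9, 9), 1)), "9")
})

test_that("halving the spacing changes probe potentials by a decreasing amount", {
  probes <- rbind(c(3.1e-3, 2.4e-3, 2.6e-3), c(1.6e-3, 3.4e-3, 2.2e-3))
  vs <- list()
  for (k in 1:3) {
    nv <- 12L * 2^(k - 1)
    h <- 4.8e-3 / nv
    g <- uniform_grid(c(nv, nv, nv), h)
    sys <- assemble_network(g)
    d <- g$dims
    ijk <- retistim:::node_ijk(d, seq_len(prod(d)))
    src <- retistim:::node_index(d, matrix(floor(d / 2), 1))
    bnd <- which(ijk[, 3] == 0)
    sol <- solve_unit_field(sys, src, bnd, method = "pcg", tol = 1e-10)
    vs[[k]] <- potential_at(sol, g, probes)
  }
  d1 <- max(abs(vs[[2]] - vs[[1]]))
  d2 <- max(abs(vs[[3]] - vs[[2]]))
  expect_lt(d2, d1)
})

test_that("electrode node sets must be disjoint and non-empty", {
  g <- uniform_grid(c(5, 5, 5), 0.5e-3)
  sys <- assemble_network(g)
  expect_error(solve_unit_field(sys, integer(0), 1L), "non-empty")
  expect_error(solve_unit_field(sys, c(1L, 2L), c(2L, 3L)), "disjoint")
})
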