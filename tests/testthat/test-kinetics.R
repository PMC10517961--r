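test_that("rate forms evaluate correctly, including the linoid singularity", {
  # removable singularity: k (V - V0) / (1 - exp(-(V - V0)/s)) -> k s
  p <- list(a = 0.6, v0 = -30, b = 10)
  expect_equal(rate_eval("linoid", p, -30), 0.6 * 10)
  expect_equal(rate_eval("linoid", p, -30 + 1e-9), 6, tolerance = 1e-6)
  expect_equal(rate_eval("exp", list(a = 20, v0 = -55, b = -18), -55), 20)
  expect_equal(rate_eval("sigmoid", list(a = 1, v0 = -30, b = 6), -30), 0.5)
  expect_equal(rate_eval("gausstau", list(a = 4, v0 = -30, b = 20, c = 1),
                         -30), 5)
  expect_error(rate_eval("mystery", p, 0), "unknown")
})

test_that("gating update has the exponential-Euler fixed point and asymptote", {
  gate <- rgc_kinetics()$channels[[1]]$gates[[1]]  # Na activation
  it <- gate_inf_tau(gate, -48)
  # x = x_inf is a fixed point
  expect_equal(gating_update(it$inf, -48, 0.01, gate), it$inf,
               tolerance = 1e-14)
  # dt -> infinity drives x to x_inf
  expect_equal(gating_update(0.9, -48, 1e6, gate), it$inf, tolerance = 1e-12)
  expect_error(gating_update(0.5, NaN, 0.01, gate), "finite")
  expect_error(gating_update(0.5, -60, 0, gate), "dt")
})

test_that("gates and time constants stay admissible over the voltage range", {
  Vs <- seq(-120, 60, by = 1)
  for (reg in list(bc_kinetics(), rgc_kinetics())) {
    for (ch in reg$channels) for (g in ch$gates) {
      it <- gate_inf_tau(g, Vs)
      expect_true(all(it$inf >= 0 & it$inf <= 1))
      expect_true(all(it$tau > 0))
    }
  }
  # gate trajectories remain in [0,1] under random bounded voltage input
  set.seed(11)
  gate <- bc_kinetics()$channels[[1]]$gates[[1]]
  x <- 0.3
  for (k in 1:200) {
    x <- gating_update(x, runif(1, -120, 60), runif(1, 0.001, 1), gate)
    expect_true(x >= 0 && x <= 1)
  }
})

test_that("ionic currents sum conductance x driving force", {
  reg <- rgc_kinetics()
  dens <- c(leak = 0.05)
  # zero driving force
  expect_equal(ionic_current(as.list(dens), list(), -60, reg), 0)
  # 10 mV above leak reversal: 0.05 mS/cm2 x 10 mV = 0.5 uA/cm2
  expect_equal(ionic_current(as.list(dens), list(), -50, reg), 0.5)
  # gates forced to zero leave only the leak
  dens2 <- list(leak = 0.05, Na = 100, K = 50)
  gates0 <- list(Na = c(0, 0), K = 0)
  expect_equal(ionic_current(dens2, gates0, -50, reg), 0.5)
})

test_that("the calcium pool relaxes and responds to inward current", {
  p <- rgc_kinetics()$calcium
  # equilibrium at rest with no calcium current
  expect_equal(calcium_update(p$rest, 0, 0.01, p), p$rest)
  # exponential decay toward rest (one forward-Euler step of the ODE)
  ca0 <- 5 * p$rest
  expect_equal(calcium_update(ca0, 0, 0.01, p),
               ca0 - 0.01 * (ca0 - p$rest) / p$tau)
  # sustained inward (negative) current raises calcium
  expect_gt(calcium_update(p$rest, -10, 0.01, p), p$rest)
  # floored below
  expect_gte(calcium_update(p$floor, 1e6, 1, p), p$floor)
})

test_that("exponential Euler converges to the gate ODE as dt shrinks", {
  gate <- rgc_kinetics()$channels[[2]]$gates[[1]]  # K activation
  V <- -30
  final_at <- function(dt, update) {
    x <- 0.05
    for (k in seq_len(round(2 / dt))) x <- update(x, dt)
    x
  }
  ee <- function(x, dt) gating_update(x, V, dt, gate)
  fe <- function(x, dt) {
    it <- gate_inf_tau(gate, V)
    x + dt * (it$inf - x) / it$tau
  }
  errs <- vapply(c(0.1, 0.05, 0.025), function(dt)
    abs(final_at(dt, ee) - final_at(dt, fe)), 0)
  expect_true(all(diff(errs) < 0))
})

test_that("registries round trip through the YAML schema", {
  for (reg in list(bc_kinetics(), rgc_kinetics())) {
    path <- tempfile(fileext = ".yaml")
    write_kinetics(reg, path)
    back <- read_kinetics(path)
    expect_equal(length(back$channels), length(reg$channels))
    for (k in seq_along(reg$channels)) {
      expect_identical(back$channels[[k]]$name, reg$channels[[k]]$name)
      expect_equal(back$channels[[k]]$gates, reg$channels[[k]]$gates,
                   tolerance = 1e-12)
    }
    expect_equal(back$calcium, reg$calcium, tolerance = 1e-12)
  }
  # the shipped registry files mirror the in-code defaults
  bc_file <- system.file("extdata", "kinetics_bc.yaml", package = "retistim")
  expect_equal(read_kinetics(bc_file)$channels, bc_kinetics()$channels,
               tolerance = 1e-12)
  rgc_file <- system.file("extdata", "kinetics_rgc.yaml", package = "retistim")
  expect_equal(read_kinetics(rgc_file)$channels, rgc_kinetics()$channels,
               tolerance = 1e-12)
})

test_that("the compiled gate update matches the R reference", {
  # a settled cell stepped once with a frozen voltage: the compiled gates
  # must advance exactly as the R exponential-Euler closed form
  bc <- settled_bc()
  st <- bc$state
  out <- retistim:::run_steps(bc, st, 0.05, 1L,
                              numeric(ncol(bc$densities)), c(0, 0),
                              numeric(ncol(bc$densities)), 1L)
  flat <- st$flat
  gi <- 0L
  for (ci in seq_along(flat$chans)) {
    for (g in flat$chans[[ci]]$gates) {
      gi <- gi + 1L
      live <- which(bc$densities[ci, ] > 0)
      if (!length(live)) next
      expected <- gating_update(st$gates[gi, live], st$v[live], 0.05, g)
      expect_equal(out$gates_final[gi, live], expected, tolerance = 1e-12)
    }
  }
})
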