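test_that("both standard cells settle to a quiet resting state", {
  bc <- settled_bc()
  rgc <- settled_rgc()
  # resting criterion: |dVm/dt| below 1e-4 mV/ms at every compartment
  expect_lt(bc$state$max_dvdt, 1e-4)
  expect_lt(rgc$state$max_dvdt, 1e-4)
  expect_true(all(bc$state$v > -80 & bc$state$v < -50))
  expect_true(all(rgc$state$v > -80 & rgc$state$v < -55))
  # and no spontaneous spiking over a long quiet stretch
  for (cell in list(bc, rgc)) {
    tr <- simulate_cell(cell, config = sim_config(duration = 300))
    expect_length(detect_spikes(tr), 0)
    expect_true(all(is.finite(tr$vm)))
  }
})

test_that("passive step response matches the RC closed form within 0.5%", {
  # tau = Cm / g_leak: 30.3 ms at the bipolar leak, 20 ms at the RGC leak
  for (g_l in c(0.033, 0.05)) {
    cell <- settle_cell(passive_single(g_leak = g_l),
                        sim_config(settle_tol = 1e-9))
    tau <- 1 / g_l  # ms
    area <- cell$chain$compartments$area_cm2
    i_nA <- 0.01 * area * 1e3  # 0.01 uA/cm^2 step, in nA
    tr <- simulate_cell(cell, i_inj = i_nA,
                        config = sim_config(duration = 100, dt = 0.01))
    dv_inf <- 0.01 / g_l  # mV steady deflection
    expected <- -60 + dv_inf * (1 - exp(-tr$time / tau))
    err <- max(abs(tr$vm[1, ] - expected)) / dv_inf
    expect_lt(err, 0.005)
  }
})

test_that("a spatially uniform extracellular potential does not drive the cable", {
  bc <- settled_bc()
  ve <- rep(5000, ncol(bc$densities))  # large but uniform, V/A
  tr <- simulate_cell(bc, ve, biphasic_pulse(1000, 5))
  quiet <- simulate_cell(bc, config = sim_config(duration = 20))
  expect_equal(tr$vm, quiet$vm, tolerance = 1e-12)
})

test_that("flipping waveform polarity and field sign leaves Vm unchanged", {
  bc <- settled_bc()
  ve <- linear_field(bc)
  t1 <- simulate_cell(bc, ve, biphasic_pulse(50, 2))
  t2 <- simulate_cell(bc, -ve, biphasic_pulse(50, 2, cathodic_first = FALSE))
  expect_equal(t1$vm, t2$vm, tolerance = 1e-12)
})

test_that("spike detection finds interpolated threshold crossings", {
  mk <- function(v, dt = 0.1) structure(
    list(time = (seq_along(v) - 1) * dt, vm = matrix(v, 1), record = 1L,
         stimulus = numeric(length(v)), dt = dt, detect = 1L),
    class = "membrane_trace")
  cfg <- sim_config()
  expect_length(detect_spikes(mk(rep(-65, 50)), cfg), 0)
  # single crossing from -10 to +10 between samples 3 and 4 -> t = 0.25
  v <- c(-65, -40, -10, 10, 20, -20)
  sp <- detect_spikes(mk(v), cfg)
  expect_length(sp, 1)
  expect_equal(sp, 0.25)
  # double crossing inside the refractory window counts once
  v2 <- c(-65, 10, -5, 10, -65)  # crossings at ~0.09 and ~0.23 ms
  expect_length(detect_spikes(mk(v2), cfg), 1)
  # but two crossings separated by more than the window count twice
  v3 <- c(-65, 10, rep(-65, 12), 10, -65)
  expect_length(detect_spikes(mk(v3), cfg), 2)
})

test_that("compartment refinement converges for a passive cell", {
  drive <- function(maxlen) {
    chain <- compartmentalize(build_db4_bc(), maxlen, cm = 1, ri = 100)
    tab <- bc_channel_table()
    tab$densities[, setdiff(names(tab$densities), "leak")] <- 0
    cell <- settle_cell(assign_channels(chain, tab, bc_kinetics()),
                        sim_config(settle_tol = 1e-9))
    soma <- which(cell$chain$compartments$region == "soma")[1]
    pos <- compartment_positions(cell)
    tr <- simulate_cell(cell, pos[, 3] * 1e6, biphasic_pulse(100, 5),
                        record = soma)
    tr$vm[1, ]
  }
  v1 <- drive(5); v2 <- drive(2.5); v3 <- drive(1.25)
  d1 <- max(abs(v2 - v1)); d2 <- max(abs(v3 - v2))
  expect_lt(d2, d1)
})

test_that("membrane traces have the declared shape and export to CSV", {
  bc <- settled_bc()
  cfg <- sim_config(duration = 2, dt = 0.01)
  tr <- simulate_cell(bc, config = cfg)
  expect_identical(ncol(tr$vm), length(tr$time))
  expect_gte(max(tr$time), 2)
  expect_identical(nrow(tr$vm), ncol(bc$densities))
  expect_true(all(is.finite(tr$vm)))
  path <- tempfile(fileext = ".csv")
  write_trace(tr, path)
  df <- read.csv(path)
  expect_identical(nrow(df), length(tr$time))
})
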