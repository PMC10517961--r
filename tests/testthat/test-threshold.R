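test_that("bisection agrees with an exhaustive amplitude sweep", {
  bc <- settled_bc()
  ve <- linear_field(bc)
  factory <- function(a) biphasic_pulse(a, 1)
  thr <- find_threshold(bc, ve, factory, seed = 10, tol = 0.02)
  # sweep oracle: smallest spiking amplitude on a grid of step tol * thr
  detect <- detection_compartment(bc)
  twin <- settle_cell(passive_twin(bc))
  spikes_at <- function(a) {
    tr <- simulate_cell(bc, ve, factory(a), record = detect)
    tp <- simulate_cell(twin, ve, factory(a), record = detect)
    tr$vm <- tr$vm - tp$vm + tp$vm[, 1]
    length(detect_spikes(tr, sim_config(), detect)) > 0
  }
  step <- 0.02 * thr
  grid <- seq(from = thr * 0.85, to = thr * 1.15, by = step)
  sweep_thr <- grid[which(vapply(grid, spikes_at, TRUE))[1]]
  expect_lt(abs(thr - sweep_thr), step + 1e-9)
})

test_that("doubling the field halves the threshold", {
  bc <- settled_bc()
  ve <- linear_field(bc)
  factory <- function(a) biphasic_pulse(a, 3)
  t1 <- find_threshold(bc, ve, factory, seed = 10)
  t2 <- find_threshold(bc, 2 * ve, factory, seed = 5)
  # geometric bracketing/bisection makes the scaling exact
  expect_equal(as.numeric(t2), as.numeric(t1) / 2, tolerance = 1e-9)
})

test_that("a passive cell is reported as inexcitable", {
  cell <- settle_cell(passive_twin(settled_bc()))
  expect_error(
    find_threshold(cell, linear_field(cell),
                   function(a) biphasic_pulse(a, 10), cap = 1e4),
    "inexcitable")
})

test_that("the threshold is invariant to the bracket seed", {
  bc <- settled_bc()
  ve <- linear_field(bc)
  factory <- function(a) biphasic_pulse(a, 3)
  t1 <- find_threshold(bc, ve, factory, seed = 3)
  t2 <- find_threshold(bc, ve, factory, seed = 500)
  expect_lt(abs(t1 - t2) / t1, 2 * 0.02)
})

test_that("strength-duration curves carry the duration grid and metadata", {
  bc <- settled_bc()
  ve <- linear_field(bc)
  sd <- strength_duration(bc, ve, durations = c(1, 3, 10), label = "bc",
                          electrode = "X")
  expect_identical(nrow(sd$points), 3L)
  expect_true(all(sd$points$threshold_uA > 0))
  expect_error(strength_duration(bc, ve, durations = c(3, 1)), "increasing")
  path <- tempfile(fileext = ".csv")
  write_curve(sd, path)
  expect_identical(nrow(read.csv(path)), 3L)
})

test_that("threshold ratios divide matched curves pointwise", {
  bc <- settled_bc()
  ve <- linear_field(bc)
  s1 <- strength_duration(bc, ve, durations = c(1, 10), electrode = "TES1")
  r <- threshold_ratio(s1, s1)
  expect_equal(r$points$ratio, c(1, 1))
  s2 <- strength_duration(bc, ve, durations = c(1, 3), electrode = "TES2")
  expect_error(threshold_ratio(s1, s2), "match")
  s3 <- strength_duration(bc, 2 * ve, durations = c(1, 10),
                          electrode = "TES2")
  r2 <- threshold_ratio(s1, s3)
  expect_equal(r2$points$ratio, c(2, 2), tolerance = 1e-6)
})
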