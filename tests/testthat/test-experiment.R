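tiny_config <- function(...) {
  experiment_config(
    grid = list(spacing = 0.2e-3, domain = c(10e-3, 10e-3, 10e-3)),
    eye = list(eye_centre = c(5e-3, 5e-3, 5.5e-3)),
    electrodes = list(ring_diameter = 3e-3, wire_diameter = 0.27e-3,
                      needle_offset = 1e-3, needle_length = 1.5e-3),
    durations = c(10),
    ...)
}

test_that("config validation reports named diagnostics without running", {
  expect_length(validate_config(experiment_config()), 0)
  cfg_missing <- experiment_config()
  cfg_missing$tissues$retina <- NULL
  d1 <- validate_config(cfg_missing)
  expect_true(any(grepl("retina", d1)))
  d2 <- validate_config(experiment_config(search = list(dt = -0.01,
                                                        tol = 0.02)))
  expect_true(any(grepl("timestep", d2)))
  d3 <- validate_config(experiment_config(durations = c(3, 1)))
  expect_true(any(grepl("increasing", d3)))
  # bundled configs are valid
  for (f in c("fig2b.yaml", "fig3a.yaml")) {
    cfg <- read_experiment_config(system.file("extdata", f,
                                              package = "retistim"))
    expect_length(validate_config(cfg), 0)
  }
  expect_error(read_experiment_config("no/such/file.yaml"), "not found")
})

test_that("the safety-only bundled experiment reproduces the 100 uA verdict", {
  cfg <- read_experiment_config(system.file("extdata", "fig3a.yaml",
                                            package = "retistim"))
  out1 <- file.path(tempdir(), "fig3a-run1")
  res <- run_experiment(cfg, out1, plots = FALSE)
  expect_equal(res$safety$max_safe_uA, 100)
  expect_true(file.exists(file.path(out1, "shannon.csv")))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  # determinism: identical config -> byte-identical CSV output
  out2 <- file.path(tempdir(), "fig3a-run2")
  run_experiment(cfg, out2, plots = FALSE)
  expect_identical(readLines(file.path(out1, "shannon.csv")),
                   readLines(file.path(out2, "shannon.csv")))
  m <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_identical(m$package, "retistim")
  expect_equal(m$max_safe_uA, 100)
})

test_that("a reduced end-to-end run produces curves, ratios and a manifest", {
  cfg <- tiny_config()
  out <- file.path(tempdir(), "tiny-run")
  res <- run_experiment(cfg, out, plots = FALSE)
  for (f in c("sd_bc_TES1.csv", "sd_bc_TES2.csv", "sd_rgc_TES1.csv",
              "sd_rgc_TES2.csv", "ratio_bc.csv", "ratio_rgc.csv",
              "shannon.csv", "manifest.json"))
    expect_true(file.exists(file.path(out, f)), label = f)
  rb <- read.csv(file.path(out, "ratio_bc.csv"))
  rr <- read.csv(file.path(out, "ratio_rgc.csv"))
  # bipolar selectivity for TES2 persists in the smaller domain, and the
  # bipolar cell remains the more placement-sensitive of the two
  expect_gt(rb$ratio, 1)
  expect_gt(rb$ratio, rr$ratio)
  # solver residuals are recorded and within tolerance
  m <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_true(all(unlist(m$solver_residuals) <= 1e-8))
  # invalid configs abort before any compute
  expect_error(run_experiment(experiment_config(durations = c(3, 1)),
                              tempdir()), "invalid config")
})
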