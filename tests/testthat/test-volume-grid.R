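test_that("tissue resistivity lookups return the measured values", {
  tab <- default_tissue_table()
  expect_identical(tab[["vitreous"]], 0.666)
  expect_identical(tab[["retina"]], 1.5)
  grid <- build_head_eye_model(head_eye_config())
  expect_identical(grid$resistivity_table[["vitreous"]], 0.666)
  expect_identical(grid$resistivity_table[["retina"]], 1.5)
  # every voxel label resolves to a positive resistivity
  rho <- grid_resistivity(grid)
  expect_true(all(is.finite(rho)) && all(rho > 0))
  # the layered eye is present
  used <- grid$tissues[sort(unique(as.integer(grid$labels)))]
  expect_true(all(c("cornea", "lens", "vitreous", "retina") %in% used))
})

test_that("degenerate geometry configurations are rejected", {
  expect_error(build_head_eye_model(head_eye_config(spacing = 0.3e-3)),
               "retina")
  expect_error(
    build_head_eye_model(head_eye_config(retina_thickness = 2e-3,
                                         cornea_thickness = 1.5e-3)),
    "exceed")
})

test_that("a uniform grid is homogeneous and its network has equal branches", {
  g <- uniform_grid(c(6, 6, 6), 0.2e-3)
  expect_identical(length(unique(as.integer(g$labels))), 1L)
  sys <- assemble_network(g)
  off <- sys$L@x[sys$L@x < 0]
  expect_equal(max(off), min(off))
})

test_that("voxel/world round trip is the identity for in-range indices", {
  grid <- uniform_grid(c(11, 9, 7), 0.33e-3)
  set.seed(7)
  ijk <- cbind(sample(0:11, 60, TRUE), sample(0:9, 60, TRUE),
               sample(0:7, 60, TRUE))
  back <- world_to_voxel(grid, voxel_to_world(grid, ijk))
  expect_identical(back, matrix(as.integer(ijk), ncol = 3L,
                                dimnames = dimnames(back)))
})

test_that("labels act only as resistivity keys", {
  # same resistivities under different tissue names -> identical network
  g1 <- uniform_grid(c(5, 5, 5), 0.1e-3, tissue = "vitreous", rho = 0.666)
  g2 <- uniform_grid(c(5, 5, 5), 0.1e-3, tissue = "gel", rho = 0.666)
  expect_equal(assemble_network(g1)$L, assemble_network(g2)$L)
})

test_that("electrode presets map to sensible disjoint node sets", {
  grid <- build_head_eye_model(head_eye_config())
  cfg <- head_eye_config()
  t1 <- tes_preset(grid, "TES1")
  t2 <- tes_preset(grid, "TES2")
  for (el in list(t1, t2)) {
    expect_gt(length(el$stimulating), 0)
    expect_gt(length(el$return), 0)
    expect_length(intersect(el$stimulating, el$return), 0)
  }
  # presets share the same grid; only the node sets differ
  expect_false(setequal(t1$stimulating, t2$stimulating))
  # TES2 stimulating ring sits on the corneal cap of the eye sphere
  pos <- node_position(grid, t2$stimulating)
  rel <- sweep(pos, 2L, cfg$eye_centre, "-")
  r <- sqrt(rowSums(rel^2))
  expect_true(all(abs(r - cfg$eye_diameter / 2) < 2 * grid$spacing))
  expect_true(all(rel[, 3L] > 0))  # anterior (corneal) side
  # TES2 return needle lies on the temporal side of the head
  npos <- node_position(grid, t2$return)
  expect_true(all(npos[, 1L] > cfg$eye_centre[1L] + cfg$eye_diameter / 2))
})

test_that("ring node count tracks circumference / spacing", {
  grid <- uniform_grid(c(50, 50, 50), 0.2e-3)
  ring <- electrode_ring(centre = c(5e-3, 5e-3, 5e-3), normal = c(0, 0, 1),
                         diameter = 3e-3)
  nodes <- place_electrode(grid, ring)
  expected <- pi * 3e-3 / 0.2e-3  # ~47
  expect_gt(length(nodes), expected * 0.7)
  expect_lt(length(nodes), expected * 1.3)
})

test_that("a one-voxel needle maps to the node nearest its tip", {
  grid <- uniform_grid(c(20, 20, 20), 0.2e-3)
  tip <- c(2.05e-3, 2.05e-3, 2.05e-3)
  needle <- electrode_needle(tip, c(0, 0, 1), exposed_length = 0.2e-3)
  nodes <- place_electrode(grid, needle)
  expect_gte(length(nodes), 1L)
  pos <- node_position(grid, nodes)
  d <- sqrt(rowSums(sweep(pos, 2L, tip, "-")^2))
  expect_lte(min(d), sqrt(3) / 2 * grid$spacing + 1e-12)
  # geometry outside the grid errors
  far <- electrode_needle(c(1, 1, 1), c(0, 0, 1), 0.2e-3)
  expect_error(place_electrode(grid, far), "intersect")
})

test_that("grid export writes labels and metadata", {
  g <- uniform_grid(c(3, 3, 3), 0.5e-3)
  dir <- file.path(tempdir(), "gridout")
  write_grid(g, dir)
  lab <- read.csv(file.path(dir, "labels.csv"))
  expect_identical(nrow(lab), 27L)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  expect_equal(meta$spacing, 0.5e-3)
})
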