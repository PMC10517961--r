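test_that("the DB4 bipolar cell has the five regions and default height", {
  m <- build_db4_bc()
  expect_setequal(unique(m$sections$region),
                  c("soma", "dendrite", "axon", "presynaptic_terminal",
                    "terminal"))
  expect_equal(sum(section_length(m)), 65)
  expect_error(build_db4_bc(axon_length = -1), "lengths")
})

test_that("rigid rotation leaves areas and axial resistances unchanged", {
  m <- build_db4_bc()
  rot <- rotation_about(c(0, 1, 0), pi / 2)
  m2 <- transform_morphology(m, rot, c(10, -3, 2))
  c1 <- compartmentalize(m, 5, cm = 1, ri = 100)$compartments
  c2 <- compartmentalize(m2, 5, cm = 1, ri = 100)$compartments
  expect_equal(c2$area_cm2, c1$area_cm2, tolerance = 1e-10)
  expect_equal(c2$r_axial_Mohm, c1$r_axial_Mohm, tolerance = 1e-10)
})

test_that("the A2 ganglion cell matches its morphometric constraints", {
  m <- build_a2_rgc()
  soma <- m$sections[m$sections$region == "soma", ]
  expect_equal(soma$d0, 20)
  ax <- m$sections[m$sections$region %in% c("AH", "SOCB", "NS", "DA"), ]
  lens <- sqrt((ax$x1 - ax$x0)^2 + (ax$y1 - ax$y0)^2 + (ax$z1 - ax$z0)^2)
  expect_equal(sum(lens), 1000)
  expect_error(build_a2_rgc(axon_lengths = c(AH = 40, SOCB = 40, NS = 90,
                                             DA = 800)), "sum")
  # dendritic tip-to-tip span is the field size within a compartment length
  den <- m$sections[m$sections$region == "dendrite", ]
  tips <- as.matrix(den[, c("x1", "y1")])
  span <- 2 * max(sqrt(rowSums(tips^2)))
  expect_lt(abs(span - 320), 10)
})

test_that("SWC files round trip with standard conventions", {
  path <- toy_swc()
  m <- read_swc(path)
  expect_identical(nrow(m$sections), 3L)  # soma + two neurite segments
  expect_setequal(unique(m$sections$region), c("soma", "dendrite"))
  neu <- m$sections[m$sections$region == "dendrite", ]
  expect_equal(sqrt((neu$x1[2] - neu$x0[2])^2 + (neu$y1[2] - neu$y0[2])^2 +
                      (neu$z1[2] - neu$z0[2])^2), 10)
  # radii are half-diameters
  expect_equal(neu$d1[1], 1.0)
  # write -> read preserves point count and radii
  out <- tempfile(fileext = ".swc")
  write_swc(m, out)
  m2 <- read_swc(out)
  p1 <- attr(m, "swc_points"); p2 <- attr(m2, "swc_points")
  expect_identical(nrow(p1), nrow(p2))
  expect_equal(p1$radius, p2$radius)
  # malformed files are rejected
  bad <- tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 2", "2 3 0 0 5 0.5 1"), bad)  # cycle
  expect_error(read_swc(bad), "cyclic")
  bad2 <- tempfile(fileext = ".swc")
  writeLines("1 9 0 0 0 5 -1", bad2)  # unmapped structure type
  expect_error(read_swc(bad2), "structure type")
})

test_that("compartmentalization reproduces cylinder geometry", {
  secs <- data.frame(region = "axon", parent = 0L, x0 = 0, y0 = 0, z0 = 0,
                     x1 = 0, y1 = 0, z1 = 100, d0 = 1, d1 = 1)
  m <- morphology(secs, "cyl")
  one <- compartmentalize(m, 101, cm = 1, ri = 100)$compartments
  # axial resistance of the full cylinder: Ri L / (pi r^2) = 127.3 Mohm
  R_full <- 100 * 100e-4 / (pi * (0.5e-4)^2) / 1e6
  expect_equal(one$r_half_prox + one$r_half_dist, R_full, tolerance = 1e-10)
  expect_equal(R_full, 127.3, tolerance = 1e-3)
  # membrane area pi d L = 3.14e-6 cm^2
  expect_equal(one$area_cm2, pi * 1e-4 * 100e-4, tolerance = 1e-12)
  # split into 10: series sum of all half-resistances matches within 0.1%
  ten <- compartmentalize(m, 10, cm = 1, ri = 100)$compartments
  expect_identical(nrow(ten), 10L)
  expect_equal(sum(ten$r_half_prox + ten$r_half_dist), R_full,
               tolerance = 1e-3)
  # per-section area within 1% of the cylinder area
  expect_equal(sum(ten$area_cm2), pi * 1e-4 * 100e-4, tolerance = 0.01)
})

test_that("channel assignment distributes the table densities by region", {
  bc <- settled_bc()
  df <- bc$chain$compartments
  ax <- which(df$region == "axon")[1]
  expect_equal(unname(bc$densities["Na", ax]), 1000)
  expect_equal(unname(bc$densities["Kfast", ax]), 2)
  expect_equal(unname(bc$densities["leak", ax]), 0.033)
  expect_equal(unname(bc$densities["Kslow", ax]), 0)
  expect_equal(unname(bc$densities["CaL", ax]), 0)

  rgc <- settled_rgc()
  dfr <- rgc$chain$compartments
  socb <- which(dfr$region == "SOCB")[1]
  expect_equal(unname(rgc$densities["Na", socb]), 2400)   # 2.4 S/cm^2 in mS/cm^2
  expect_equal(unname(rgc$densities["K", socb]), 800)
  expect_equal(unname(rgc$densities["KA", socb]), 3 * 800)
  # uniform leak 0.05 mS/cm^2 with -60 mV reversal
  expect_true(all(rgc$densities["leak", ] == 0.05))
  expect_equal(rgc$leak_erev, -60)

  # unknown region tags are rejected
  chain <- compartmentalize(build_db4_bc(), 5, 1, 100)
  chain$compartments$region[1] <- "mystery"
  expect_error(assign_channels(chain, bc_channel_table()), "mystery")
})
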