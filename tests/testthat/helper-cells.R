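# Small builders shared across test files. Fixtures are generated in code;
# nothing is read from disk.

# single-compartment passive cell with a given leak density (mS/cm^2)
passive_single <- function(g_leak = 0.033, cm = 1, ri = 100,
                           diam = 10, len = 10, erev = -60) {
  secs <- data.frame(region = "soma", parent = 0L,
                     x0 = 0, y0 = 0, z0 = 0, x1 = 0, y1 = 0, z1 = len,
                     d0 = diam, d1 = diam)
  m <- morphology(secs, "toy")
  chain <- compartmentalize(m, max_compartment_length = len + 1, cm = cm,
                            ri = ri)
  tab <- channel_table(data.frame(leak = g_leak, row.names = "soma"),
                       units = "mS/cm2", leak_erev = erev)
  kin <- bc_kinetics()  # leak entry is all that gets used
  assign_channels(chain, tab, kin)
}

# default bipolar cell, settled once and cached for the whole test run
.cells <- new.env(parent = emptyenv())

settled_bc <- function() {
  if (is.null(.cells$bc)) {
    chain <- compartmentalize(build_db4_bc(), 5, cm = 1, ri = 100)
    .cells$bc <- settle_cell(assign_channels(chain, bc_channel_table()))
  }
  .cells$bc
}

settled_rgc <- function() {
  if (is.null(.cells$rgc)) {
    chain <- compartmentalize(build_a2_rgc(), 10, cm = 1, ri = 110)
    .cells$rgc <- settle_cell(assign_channels(chain, rgc_channel_table()))
  }
  .cells$rgc
}

# synthetic linear extracellular field along the cell's own axis, V/A per
# metre of the coordinate; strong enough that default seeds bracket quickly
linear_field <- function(cell, axis = 3, scale = 1e6) {
  pos <- compartment_positions(cell)
  pos[, axis] * scale
}

# a three-point toy SWC file written to a temp path
toy_swc <- function(path = tempfile(fileext = ".swc")) {
  writeLines(c(
    "# toy cell",
    "1 1 0 0 0 5 -1",
    "2 3 0 0 5 0.5 1",
    "3 3 0 0 15 0.5 2"), path)
  path
}
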