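# The reduced-model TES pipeline at its default study conditions: head-eye
# grid at 0.2 mm, TES1/TES2 unit fields, both cells, biphasic
# strength-duration curves for each cell x electrode configuration and
# monophasic curves under TES2. Computed once per test run (a few minutes)
# and shared by the acceptance tests.

.pipeline <- new.env(parent = emptyenv())

tes_pipeline <- function() {
  if (!is.null(.pipeline$res)) return(.pipeline$res)
  cfg <- experiment_config()
  grid <- build_head_eye_model(retistim:::head_eye_config_from(cfg))
  fields <- tes_fields(grid, cfg)
  cells <- standard_cells(cfg)
  cap <- cfg$search$cap
  ve <- list()
  for (cl in c("bc", "rgc")) {
    pl <- cell_placement(cfg, cl)
    pos <- compartment_positions(cells[[cl]], pl$at, pl$rotation)
    for (nm in c("TES1", "TES2"))
      ve[[paste(cl, nm)]] <- potential_at(fields[[nm]], grid, pos)
  }
  bi <- list()
  for (cl in c("bc", "rgc")) for (nm in c("TES1", "TES2"))
    bi[[paste(cl, nm)]] <- strength_duration(
      cells[[cl]], ve[[paste(cl, nm)]], kind = "biphasic", label = cl,
      electrode = nm, seed = cfg$search$seed, cap = cap)
  mono <- list()
  for (cl in c("bc", "rgc"))
    mono[[cl]] <- strength_duration(
      cells[[cl]], ve[[paste(cl, "TES2")]], kind = "monophasic", label = cl,
      electrode = "TES2", seed = cfg$search$seed, cap = cap)
  .pipeline$res <- list(cfg = cfg, grid = grid, fields = fields,
                        cells = cells, ve = ve, biphasic = bi,
                        monophasic = mono)
  .pipeline$res
}
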