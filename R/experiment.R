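#' Default experiment configuration
#'
#' A single list drives an end-to-end run: grid geometry, electrode
#' presets, the cells to simulate, waveform kind and duration grid,
#' threshold-search settings and the Shannon safety block. Bundled YAML
#' configs mirroring this structure live in `inst/extdata/`
#' (`fig2b.yaml`: TES1/TES2 threshold-ratio curves; `fig3a.yaml`: the
#' Shannon chart).
#'
#' @param ... named overrides merged over the defaults (nested lists are
#'   merged recursively).
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(...) {
  base <- list(
    name = "experiment",
    grid = list(spacing = 0.2e-3, domain = c(20e-3, 20e-3, 20e-3)),
    eye = list(),                      # head_eye_config() overrides
    tissues = as.list(default_tissue_table()),
    electrodes = list(ring_diameter = 3e-3, wire_diameter = 0.27e-3,
                      needle_offset = 2e-3, needle_length = 5e-3),
    configs = c("TES1", "TES2"),
    cells = c("bc", "rgc"),
    cell_offset = 0.5e-3,              # lateral offset of the retinal site, m
    kinetics = list(bc = "default", rgc = "default"),
    waveform = list(kind = "biphasic"),
    durations = c(0.1, 0.3, 1, 3, 10, 25),
    search = list(seed = 10, tol = 0.02, dt = 0.01, cap = 1e9),
    solver = list(tol = 1e-8, maxit = 20000),
    safety = list(amplitudes = c(20, 50, 100, 200, 300, 400),
                  phase_ms = 10, inner_diameter_mm = 3,
                  wire_diameter_mm = 0.27, contact_fraction = 1,
                  k_limit = 1.5),
    seed = 1)
  cfg <- utils::modifyList(base, list(...))
  class(cfg) <- "experiment_config"
  cfg
}

#' Read an experiment config from YAML or JSON
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                        simplifyVector = TRUE)
  else yaml::read_yaml(path)
  # yaml keeps mixed int/double sequences as lists; flatten numeric blocks
  num <- function(x) if (is.null(x) || !length(x)) numeric(0) else
    as.numeric(unlist(x))
  if (!is.null(y$durations)) y$durations <- num(y$durations)
  if (!is.null(y$grid$domain)) y$grid$domain <- num(y$grid$domain)
  if (!is.null(y$safety$amplitudes)) y$safety$amplitudes <- num(y$safety$amplitudes)
  for (f in c("cells", "configs"))
    if (!is.null(y[[f]])) y[[f]] <- as.character(unlist(y[[f]]))
  do.call(experiment_config, y)
}

#' Validate an experiment config without running it
#'
#' @param config an [experiment_config()], or a path to one.
#' @return Character vector of diagnostics (empty when valid).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_experiment_config(config)
  d <- character(0)
  say <- function(...) d <<- c(d, paste0(...))
  g <- config$grid
  if (!is.numeric(g$spacing) || g$spacing <= 0)
    say("grid.spacing must be > 0")
  if (length(g$domain) != 3L || any(g$domain <= 0))
    say("grid.domain must be three positive lengths")
  tt <- unlist(config$tissues)
  if (!length(tt)) say("tissue table is empty")
  for (nm in c("muscle", "vitreous", "retina", "cornea", "lens"))
    if (!nm %in% names(tt)) say("missing tissue resistivity: ", nm)
  if (any(tt <= 0)) say("tissue resistivities must be > 0")
  if (is.numeric(g$spacing) && is.numeric(config$eye$retina_thickness %||% 0.2e-3) &&
      g$spacing > (config$eye$retina_thickness %||% 0.2e-3))
    say("grid.spacing exceeds the retina thickness")
  if (!all(config$configs %in% c("TES1", "TES2")))
    say("configs must be a subset of TES1/TES2")
  if (!all(config$cells %in% c("bc", "rgc")))
    say("cells must be a subset of bc/rgc")
  if (length(config$durations) &&
      (any(config$durations <= 0) || is.unsorted(config$durations, strictly = TRUE)))
    say("durations must be positive and strictly increasing")
  if (!is.numeric(config$search$dt) || config$search$dt <= 0)
    say("search.dt must be > 0 (negative or zero timestep)")
  if (!is.numeric(config$search$tol) || config$search$tol <= 0)
    say("search.tol must be > 0")
  s <- config$safety
  if (length(s$amplitudes) == 0 || any(s$amplitudes <= 0))
    say("safety.amplitudes must be positive")
  if (!is.numeric(s$phase_ms) || s$phase_ms <= 0)
    say("safety.phase_ms must be > 0")
  for (cl in config$cells) {
    k <- config$kinetics[[cl]]
    if (!is.null(k) && !identical(k, "default") && !file.exists(k))
      say("kinetics file for ", cl, " not found: ", k)
  }
  d
}

head_eye_config_from <- function(config) {
  args <- utils::modifyList(
    list(spacing = config$grid$spacing, domain = config$grid$domain,
         tissues = unlist(config$tissues)),
    config$eye)
  do.call(head_eye_config, args)
}

#' Build the two standard retinal cells
#'
#' Spiking DB4 bipolar cell (5 um compartments, Cm 1 uF/cm^2, Ri 100 ohm
#' cm) and A2 ganglion cell (10 um compartments, Ri 110 ohm cm), with
#' their default channel tables and kinetics, settled to rest.
#'
#' @param config an [experiment_config()].
#' @param settle settle the cells to rest (default TRUE).
#' @return named list of `cable_cell`s.
#' @export
standard_cells <- function(config = experiment_config(), settle = TRUE) {
  sim <- sim_config(dt = config$search$dt)
  out <- list()
  kin <- function(which, default) {
    k <- config$kinetics[[which]]
    if (is.null(k) || identical(k, "default")) default else read_kinetics(k)
  }
  if ("bc" %in% config$cells) {
    chain <- compartmentalize(build_db4_bc(), max_compartment_length = 5,
                              cm = 1, ri = 100)
    out$bc <- assign_channels(chain, bc_channel_table(),
                              kin("bc", bc_kinetics()))
    if (settle) out$bc <- settle_cell(out$bc, sim)
  }
  if ("rgc" %in% config$cells) {
    chain <- compartmentalize(build_a2_rgc(), max_compartment_length = 10,
                              cm = 1, ri = 110)
    out$rgc <- assign_channels(chain, rgc_channel_table(),
                               kin("rgc", rgc_kinetics()))
    if (settle) out$rgc <- settle_cell(out$rgc, sim)
  }
  out
}

#' World placement of the modelled central-retina cells
#'
#' Both cells sit at the central-retina site on the eye axis opposite the
#' cornea, shifted laterally (temporal, +x) by `config$cell_offset`. The
#' bipolar cell runs radially with its dendritic apex 15 um vitread of the
#' scleral retinal boundary - in a degenerated retina the photoreceptor
#' layer is lost, so the inner nuclear layer abuts the outer boundary. The
#' ganglion cell lies in the tangential plane with its soma near the
#' vitread retinal surface and its axon running nasally, toward the optic
#' disc on the eye axis.
#'
#' @param config an [experiment_config()].
#' @param cell `"bc"` or `"rgc"`.
#' @return list with `at` (m) and `rotation` for
#'   [compartment_positions()].
#' @export
cell_placement <- function(config, cell = c("bc", "rgc")) {
  cell <- match.arg(cell)
  gc <- head_eye_config_from(config)
  R <- gc$eye_diameter / 2
  z_outer <- gc$eye_centre[3L] - R                          # scleral surface
  z_inner <- z_outer + gc$retina_thickness                  # vitread surface
  x <- gc$eye_centre[1L] + config$cell_offset
  y <- gc$eye_centre[2L]
  if (cell == "bc") {
    # local +z (terminal -> dendrite) maps to world -z (sclerad)
    rot <- rotation_about(c(1, 0, 0), pi)
    h_bc <- 65e-6
    at <- c(x, y, z_outer + 15e-6 + h_bc)
    list(at = at, rotation = rot)
  } else {
    at <- c(x, y, z_inner - 15e-6)  # soma centre in the ganglion cell layer
    # axon runs nasally (-x), toward the optic disc on the eye axis
    list(at = at, rotation = rotation_about(c(0, 0, 1), pi))
  }
}

#' Solve the unit-current field for the requested electrode presets
#'
#' @param grid a grid from [build_head_eye_model()].
#' @param config an [experiment_config()].
#' @param names electrode configurations to solve (subset of
#'   `config$configs`).
#' @return named list of [solve_unit_field()] solutions with electrode
#'   sets attached.
#' @export
tes_fields <- function(grid, config = experiment_config(),
                       names = config$configs) {
  sys <- assemble_network(grid)
  out <- list()
  for (nm in names) {
    el <- tes_preset(grid, nm,
                     ring_diameter = config$electrodes$ring_diameter,
                     wire_diameter = config$electrodes$wire_diameter,
                     needle_offset = config$electrodes$needle_offset,
                     needle_length = config$electrodes$needle_length)
    sol <- solve_unit_field(sys, el$stimulating, el$return,
                            tol = config$solver$tol,
                            maxit = config$solver$maxit, method = "pcg")
    attr(sol, "electrodes") <- el
    out[[nm]] <- sol
  }
  out
}

#' Run an end-to-end experiment
#'
#' Builds the head-eye model, solves the unit-current field for each
#' electrode configuration, simulates the selected cells to obtain
#' strength-duration curves and TES1/TES2 threshold ratios, computes the
#' Shannon safety chart, and writes everything (CSV curves, PNG figures, a
#' JSON manifest with solver residuals and a config hash) to `out_dir`.
#' Rerunning with an identical config reproduces identical CSV numbers:
#' every stage is deterministic.
#'
#' @param config an [experiment_config()] or path to one.
#' @param out_dir output directory.
#' @param plots write PNG figures (default TRUE).
#' @return (invisibly) list with the grid, fields, cells, curves, ratios
#'   and safety results.
#' @export
run_experiment <- function(config = experiment_config(), out_dir,
                           plots = TRUE) {
  if (is.character(config)) config <- read_experiment_config(config)
  diag <- validate_config(config)
  if (length(diag))
    stop("invalid config:\n  ", paste(diag, collapse = "\n  "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("experiment stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  result <- list(config = config)

  want_thresholds <- length(config$cells) && length(config$durations) &&
    length(config$configs)
  if (want_thresholds) {
    grid <- stage("grid", build_head_eye_model(head_eye_config_from(config)))
    fields <- stage("field", tes_fields(grid, config))
    cells <- stage("cells", standard_cells(config))
    simc <- sim_config(dt = config$search$dt)

    curves <- list()
    ratios <- list()
    for (cl in names(cells)) {
      pl <- cell_placement(config, cl)
      pos <- compartment_positions(cells[[cl]], pl$at, pl$rotation)
      percfg <- list()
      for (nm in names(fields)) {
        ve <- potential_at(fields[[nm]], grid, pos)
        percfg[[nm]] <- stage("thresholds", strength_duration(
          cells[[cl]], ve, durations = config$durations,
          kind = config$waveform$kind, label = cl, electrode = nm,
          seed = config$search$seed, tol = config$search$tol,
          cap = config$search$cap %||% 1e6, config = simc))
        write_curve(percfg[[nm]],
                    file.path(out_dir, paste0("sd_", cl, "_", nm, ".csv")))
      }
      curves[[cl]] <- percfg
      if (all(c("TES1", "TES2") %in% names(percfg))) {
        ratios[[cl]] <- threshold_ratio(percfg$TES1, percfg$TES2)
        write_curve(ratios[[cl]],
                    file.path(out_dir, paste0("ratio_", cl, ".csv")))
      }
    }
    result$grid <- grid
    result$fields <- fields
    result$cells <- cells
    result$curves <- curves
    result$ratios <- ratios
    if (plots && length(ratios)) {
      grDevices::png(file.path(out_dir, "threshold_ratios.png"),
                     width = 700, height = 500)
      on.exit(grDevices::dev.off(), add = TRUE)
      first <- TRUE
      for (cl in names(ratios)) {
        p <- ratios[[cl]]$points
        if (first) {
          graphics::plot(p$duration_ms, p$ratio, log = "xy", type = "b",
                         pch = 16, xlab = "pulse duration (ms)",
                         ylab = "threshold ratio TES1/TES2",
                         ylim = range(unlist(lapply(ratios, function(r)
                           r$points$ratio))))
          first <- FALSE
        } else graphics::lines(p$duration_ms, p$ratio, type = "b", pch = 1)
      }
      graphics::abline(h = 1, lty = 2)
    }
  }

  s <- config$safety
  area <- ring_electrode_area(s$inner_diameter_mm, s$wire_diameter_mm,
                              s$contact_fraction %||% 1)
  chart <- stage("safety", shannon_chart(s$amplitudes, s$phase_ms, area))
  verdict <- stage("safety",
                   max_safe_amplitude(s$amplitudes, s$phase_ms, area,
                                      s$k_limit))
  cdf <- as.data.frame(chart)
  cdf[] <- lapply(cdf, function(x) signif(x, 9))
  write.csv(cdf, file.path(out_dir, "shannon.csv"), row.names = FALSE)
  if (plots) {
    grDevices::png(file.path(out_dir, "shannon.png"), width = 600,
                   height = 500)
    plot(chart)
    grDevices::dev.off()
  }
  result$safety <- list(chart = chart, max_safe_uA = verdict,
                        area_cm2 = area)

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "retistim",
    version = as.character(utils::packageVersion("retistim")),
    config_hash = config_hash(config),
    solver_residuals = if (want_thresholds)
      lapply(result$fields, `[[`, "residual") else NULL,
    max_safe_uA = verdict)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(cfg_json, file.path(out_dir, "config.json"))
  invisible(result)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), f)
  unname(tools::md5sum(f))
}
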