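#' Simulation configuration
#'
#' @param dt timestep, ms.
#' @param duration total simulated time after the settle period, ms. If
#'   `NULL`, [simulate_cell()] uses the waveform span plus `post` ms.
#' @param post extra time simulated after the waveform ends, ms.
#' @param settle_tol resting-state criterion: settling stops once
#'   `max |dVm/dt|` over all compartments falls below this (mV/ms).
#' @param settle_max settle time cap, ms.
#' @param spike_threshold detection threshold, mV (within (-40, 40)).
#' @param refractory minimum spacing between detected spikes, ms.
#' @param v_init initial membrane potential before settling, mV.
#' @export
sim_config <- function(dt = 0.01, duration = NULL, post = 10,
                       settle_tol = 1e-5, settle_max = 2000,
                       spike_threshold = 0, refractory = 1,
                       v_init = -65) {
  stopifnot(dt > 0, settle_max >= 0)
  if (spike_threshold <= -40 || spike_threshold >= 40)
    stop("spike detection threshold must lie within (-40, 40) mV")
  structure(list(dt = dt, duration = duration, post = post,
                 settle_tol = settle_tol, settle_max = settle_max,
                 spike_threshold = spike_threshold, refractory = refractory,
                 v_init = v_init),
            class = "sim_config")
}

# flatten a kinetics registry for the C++ stepper, in the channel order of
# the cell's density matrix
flatten_registry <- function(registry, channel_names) {
  form_code <- c(linoid = 1, "exp" = 2, sigmoid = 3, const = 4, gausstau = 5)
  chans <- registry$channels[match(channel_names,
                                   vapply(registry$channels, `[[`, "", "name"))]
  erev <- vapply(chans, function(ch)
    if (identical(ch$erev, "ca_nernst")) NA_real_ else as.numeric(ch$erev), 0)
  cadep <- vapply(chans, function(ch) as.integer(!is.null(ch$ca_gate)), 0L)
  kd <- vapply(chans, function(ch) ch$ca_gate$kd %||% 1, 0)
  hill <- vapply(chans, function(ch) ch$ca_gate$hill %||% 1, 0)
  carries <- vapply(chans, function(ch) as.integer(isTRUE(ch$carries_ca)), 0L)
  gate_channel <- integer(0)
  rows <- list()
  for (ci in seq_along(chans)) {
    for (g in chans[[ci]]$gates) {
      gate_channel <- c(gate_channel, ci - 1L)
      rows[[length(rows) + 1L]] <-
        c(g$exponent, if (g$mode == "ab") 0 else 1,
          form_code[[g$f1$form]], g$f1$a, g$f1$v0, g$f1$b, g$f1$c,
          form_code[[g$f2$form]], g$f2$a, g$f2$v0, g$f2$b, g$f2$c)
    }
  }
  gate_params <- if (length(rows)) do.call(rbind, rows) else
    matrix(0, 0, 12)
  list(erev = erev, cadep = cadep, kd = kd, hill = hill,
       carries_ca = carries, gate_channel = gate_channel,
       gate_params = gate_params,
       chans = chans)
}

cell_arrays <- function(cell) {
  df <- cell$chain$compartments
  list(parent = as.integer(df$parent) - 1L,  # -1 for root
       g_axial = ifelse(df$parent == 0L, 0, 1 / df$r_axial_Mohm),  # uS
       cap_nF = cell$chain$cm * df$area_cm2 * 1e3,
       area = df$area_cm2)
}

init_state <- function(cell, v_init) {
  flat <- flatten_registry(cell$kinetics, rownames(cell$densities))
  ngate <- length(flat$gate_channel)
  n <- ncol(cell$densities)
  gates <- matrix(0, ngate, n)
  gi <- 0L
  for (ci in seq_along(flat$chans)) {
    for (g in flat$chans[[ci]]$gates) {
      gi <- gi + 1L
      gates[gi, ] <- gate_inf_tau(g, v_init)$inf
    }
  }
  needs_ca <- any(vapply(flat$chans, function(ch)
    isTRUE(ch$carries_ca) || !is.null(ch$ca_gate), TRUE))
  list(v = rep(v_init, n), gates = gates,
       ca = if (needs_ca) rep(cell$kinetics$calcium$rest, n) else numeric(0),
       flat = flat)
}

run_steps <- function(cell, state, dt, nsteps, ve_unit, wave, iinj, record) {
  arr <- cell_arrays(cell)
  .cable_step(arr$parent, arr$g_axial, arr$cap_nF, arr$area,
              cell$densities, state$flat[c("erev", "cadep", "kd", "hill",
                                           "carries_ca", "gate_channel",
                                           "gate_params")],
              state$v, state$gates, state$ca, dt, as.integer(nsteps),
              ve_unit, wave, iinj, as.integer(record) - 1L,
              cell$kinetics$calcium)
}

#' Settle a cell to its resting state
#'
#' Integrates with zero stimulus until `max |dVm/dt|` over all compartments
#' drops below `settle_tol` (or the settle cap is reached, with a warning).
#' The converged state is cached on the cell and reused by every
#' subsequent [simulate_cell()] call.
#'
#' @param cell a `cable_cell`.
#' @param config a [sim_config()].
#' @return The cell with a `$state` field (`v`, `gates`, `ca`, plus the
#'   achieved `max_dvdt`).
#' @export
settle_cell <- function(cell, config = sim_config()) {
  state <- init_state(cell, config$v_init)
  n <- ncol(cell$densities)
  dt <- config$dt
  chunk <- 50  # ms
  t <- 0
  zero_ve <- numeric(n)
  repeat {
    nst <- ceiling(chunk / dt)
    out <- run_steps(cell, state, dt, nst, zero_ve, numeric(nst + 1L),
                     zero_ve, seq_len(n))
    dv <- abs(out$trace[, nst + 1L] - out$trace[, nst]) / dt
    state$v <- out$v_final
    state$gates <- out$gates_final
    if (length(state$ca)) state$ca <- out$ca_final
    t <- t + chunk
    if (max(dv) < config$settle_tol) break
    if (t >= config$settle_max) {
      warning("cell did not reach rest within ", config$settle_max,
              " ms (max |dV/dt| = ", format(max(dv), digits = 3), " mV/ms)")
      break
    }
  }
  cell$state <- list(v = state$v, gates = state$gates, ca = state$ca,
                     flat = state$flat, max_dvdt = max(dv), settle_ms = t)
  cell
}

#' Simulate a cell under extracellular and/or injected current drive
#'
#' Solves `Cm dVm_i/dt = -I_ion,i + sum_j ((Vm_j + Ve_j) - (Vm_i + Ve_i)) / R_ij`
#' with `Ve_i(t) = waveform(t) x` the unit-current extracellular potential
#' at compartment `i` (quasi-static scaling), by the semi-implicit scheme
#' described in the package vignette. The cell is settled first (cached).
#'
#' @param cell a `cable_cell`, ideally pre-settled with [settle_cell()].
#' @param ve_unit extracellular potential per unit current at each
#'   compartment, in V/A (as returned by [potential_at()]); `NULL` for none.
#' @param wave a [waveform()] (amplitude in uA); `NULL` for none.
#' @param i_inj steady intracellular current injection per compartment, nA
#'   (scalar for the soma/root, or a full vector); 0 for none.
#' @param config a [sim_config()].
#' @param record compartments to record (default: all).
#' @return A `membrane_trace`: `time` (ms), `vm` (compartments x samples,
#'   mV), the stimulus echo and bookkeeping fields.
#' @export
simulate_cell <- function(cell, ve_unit = NULL, wave = NULL, i_inj = 0,
                          config = sim_config(), record = NULL) {
  n <- ncol(cell$densities)
  if (is.null(cell$state)) cell <- settle_cell(cell, config)
  state <- cell$state
  dt <- config$dt

  dur <- config$duration
  if (is.null(dur))
    dur <- (if (!is.null(wave)) waveform_span(wave) else 0) + config$post
  nsteps <- ceiling(dur / dt)

  if (is.null(ve_unit)) ve_mV <- numeric(n)
  else {
    stopifnot(length(ve_unit) == n)
    # V/A * uA -> uV; convert to mV per uA of waveform current
    ve_mV <- ve_unit * 1e-3
  }
  wv <- if (is.null(wave)) numeric(nsteps + 1L) else
    sample_waveform(wave, dt, nsteps)
  iinj <- if (length(i_inj) == 1L) {
    v <- numeric(n); v[which(cell$chain$compartments$parent == 0L)] <- i_inj; v
  } else {
    stopifnot(length(i_inj) == n); as.numeric(i_inj)
  }
  if (is.null(record)) record <- seq_len(n)

  out <- run_steps(cell, state, dt, nsteps, ve_mV, wv, iinj, record)
  structure(list(time = (0:nsteps) * dt,
                 vm = out$trace,
                 record = record,
                 stimulus = wv,
                 dt = dt,
                 detect = detection_compartment(cell),
                 config = config),
            class = "membrane_trace")
}

#' @method print membrane_trace
#' @export
print.membrane_trace <- function(x, ...) {
  cat("<membrane_trace> ", nrow(x$vm), " compartments x ",
      length(x$time), " samples (", format(max(x$time)), " ms)\n", sep = "")
  invisible(x)
}

#' @export
plot.membrane_trace <- function(x, compartment = NULL, ...) {
  if (is.null(compartment)) compartment <- match(x$detect, x$record)
  if (is.na(compartment)) compartment <- 1L
  graphics::plot(x$time, x$vm[compartment, ], type = "l",
                 xlab = "time (ms)", ylab = "Vm (mV)", ...)
  invisible(x)
}

#' Detect action potentials in a trace
#'
#' Upward crossings of the detection threshold at one compartment,
#' separated by at least the refractory window; crossing times are linearly
#' interpolated between samples.
#'
#' @param trace a `membrane_trace`.
#' @param config a [sim_config()] providing threshold and refractory window.
#' @param compartment compartment to inspect (default: the cell's detection
#'   compartment).
#' @return Numeric vector of spike times (ms), possibly empty.
#' @export
detect_spikes <- function(trace, config = sim_config(), compartment = NULL) {
  if (is.null(compartment)) compartment <- trace$detect
  row <- match(compartment, trace$record)
  if (is.na(row)) stop("compartment ", compartment, " was not recorded")
  v <- trace$vm[row, ]
  thr <- config$spike_threshold
  up <- which(v[-length(v)] < thr & v[-1L] >= thr)
  if (!length(up)) return(numeric(0))
  tms <- trace$time[up] +
    (thr - v[up]) / (v[up + 1L] - v[up]) * trace$dt
  # enforce the refractory window sequentially
  out <- numeric(0)
  last <- -Inf
  for (t in tms) {
    if (t - last >= config$refractory) {
      out <- c(out, t)
      last <- t
    }
  }
  out
}

#' Export a trace as CSV (time, stimulus echo, Vm per compartment)
#' @param trace a `membrane_trace`.
#' @param path output path.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time_ms = trace$time, stimulus_uA = trace$stimulus,
                   t(trace$vm))
  names(df)[-(1:2)] <- paste0("vm_", trace$record)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
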