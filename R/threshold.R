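#' Find the activation threshold of a cell under a stimulus family
#'
#' The threshold is the lowest stimulus amplitude that elicits at least
#' one action potential at the cell's detection compartment, within the
#' window from stimulus onset to `post` ms after stimulus end. The search
#' brackets the threshold by doubling from a seed amplitude until a spike
#' occurs (capped), then narrows the bracket by geometric bisection until
#' its relative width is below `tol`; the upper end (guaranteed
#' suprathreshold) is returned. Because the extracellular drive is linear
#' in amplitude, the geometric search makes the result scale exactly
#' inversely with any uniform scaling of the field.
#'
#' @param cell a settled `cable_cell`.
#' @param ve_unit per-compartment extracellular potential, V/A.
#' @param waveform_factory function `amplitude -> waveform`; e.g.
#'   `function(a) biphasic_pulse(a, 10)`.
#' @param seed starting amplitude for the bracket search, uA.
#' @param tol relative bracket width at termination.
#' @param cap amplitude cap, uA; no spike at the cap raises an
#'   "inexcitable" error.
#' @param config a [sim_config()].
#' @param artifact_subtract remove the linear (passive) stimulus artifact
#'   before spike detection by simulating a passive twin of the cell under
#'   the same drive and detecting on the active-minus-passive departure.
#'   At the large amplitudes this reduced model requires, the passive
#'   deflection at the detection compartment can itself cross the
#'   detection threshold; subtracting the linear response isolates the
#'   regenerative (action-potential) component. Subtraction preserves the
#'   exact linear scaling of the search (both components scale with
#'   amplitude).
#' @return Threshold amplitude in uA (attribute `evaluations` counts
#'   simulate calls).
#' @export
find_threshold <- function(cell, ve_unit, waveform_factory, seed = 10,
                           tol = 0.02, cap = 1e6, config = sim_config(),
                           artifact_subtract = TRUE) {
  if (is.null(cell$state)) cell <- settle_cell(cell, config)
  detect <- detection_compartment(cell)
  twin <- if (artifact_subtract) settle_cell(passive_twin(cell), config)
  nev <- 0L
  spikes_at <- function(a) {
    nev <<- nev + 1L
    w <- waveform_factory(a)
    tr <- simulate_cell(cell, ve_unit, w, config = config, record = detect)
    if (artifact_subtract) {
      tp <- simulate_cell(twin, ve_unit, w, config = config, record = detect)
      # active departure from the linear response, re-based at rest
      tr$vm <- tr$vm - tp$vm + tp$vm[, 1L]
    }
    length(detect_spikes(tr, config, detect)) > 0L
  }
  hi <- seed
  if (spikes_at(hi)) {
    # seed is suprathreshold: halve down to a subthreshold lower end
    lo <- hi / 2
    while (spikes_at(lo)) {
      hi <- lo
      lo <- lo / 2
      if (lo < seed * 1e-12)
        stop("spontaneous activity: cell spikes at effectively zero amplitude")
    }
  } else {
    lo <- hi
    repeat {
      hi <- hi * 2
      if (hi > cap)
        stop("inexcitable under this configuration: no spike up to ",
             format(cap), " uA")
      if (spikes_at(hi)) break
      lo <- hi
    }
  }
  while (hi / lo > 1 + tol) {
    mid <- sqrt(lo * hi)
    if (spikes_at(mid)) hi <- mid else lo <- mid
  }
  structure(hi, evaluations = nev)
}

#' Strength-duration curve
#'
#' One [find_threshold()] per pulse duration. For monophasic pulses the
#' threshold is classically non-increasing with duration; violations
#' beyond the search tolerance raise a warning (not an error).
#'
#' @param cell a settled `cable_cell`.
#' @param ve_unit per-compartment extracellular potential, V/A.
#' @param durations pulse (phase) durations, ms, strictly increasing.
#'   Default grid spans the modelled 0.1-25 ms range.
#' @param kind `"biphasic"` (cathodic-first, symmetric) or `"monophasic"`.
#' @param polarity for monophasic curves: `"cathodic"`, `"anodic"`, or
#'   `"best"` (default), which takes the lower threshold of the two
#'   polarities at each duration. Which polarity excites a cell under a
#'   distant surface electrode depends on the geometry of the induced
#'   field along the cell, so the polarity-free monophasic threshold is
#'   the minimum over both.
#' @param label cell identifier stored in the curve.
#' @param electrode electrode-configuration identifier (e.g. `"TES1"`).
#' @param seed,tol,cap,config passed to [find_threshold()]. Thresholds in
#'   this reduced model can exceed the default 1e6 uA search cap for the
#'   least excitable configurations; raise `cap` to keep such curves
#'   measurable.
#' @return A `strength_duration_curve` (data.frame of duration and
#'   threshold plus metadata).
#' @export
strength_duration <- function(cell, ve_unit,
                              durations = c(0.1, 0.3, 1, 3, 10, 25),
                              kind = c("biphasic", "monophasic"),
                              polarity = c("best", "cathodic", "anodic"),
                              label = cell$cell_type, electrode = "",
                              seed = 10, tol = 0.02, cap = 1e6,
                              config = sim_config()) {
  kind <- match.arg(kind)
  polarity <- match.arg(polarity)
  if (is.unsorted(durations, strictly = TRUE))
    stop("durations must be strictly increasing")
  if (is.null(cell$state)) cell <- settle_cell(cell, config)
  pols <- if (kind == "biphasic") list(NULL) else
    switch(polarity, best = list("cathodic", "anodic"), list(polarity))
  thr <- numeric(length(durations))
  last <- rep(seed, length(pols))
  for (k in seq_along(durations)) {
    pw <- durations[k]
    cand <- rep(NA_real_, length(pols))
    for (p in seq_along(pols)) {
      factory <- if (kind == "biphasic")
        function(a) biphasic_pulse(a, pw) else
        function(a) suppressWarnings(monophasic_pulse(a, pw, pols[[p]]))
      cand[p] <- tryCatch(
        find_threshold(cell, ve_unit, factory, seed = last[p], tol = tol,
                       cap = cap, config = config),
        error = function(e) {
          # one polarity may be inexcitable; only fail if all are
          if (length(pols) > 1L && grepl("inexcitable", conditionMessage(e)))
            NA_real_ else stop(e)
        })
      if (!is.na(cand[p])) last[p] <- cand[p]
    }
    if (all(is.na(cand)))
      stop("inexcitable under this configuration: no spike up to ",
           format(cap), " uA at ", pw, " ms")
    thr[k] <- min(cand, na.rm = TRUE)
  }
  if (kind == "monophasic" &&
      any(diff(thr) > tol * thr[-length(thr)] * 2))
    warning("monophasic strength-duration curve is not non-increasing ",
            "beyond the search tolerance")
  structure(list(points = data.frame(duration_ms = durations,
                                     threshold_uA = thr),
                 cell = label, electrode = electrode, kind = kind,
                 tol = tol),
            class = "strength_duration_curve")
}

#' @method print strength_duration_curve
#' @export
print.strength_duration_curve <- function(x, ...) {
  cat("<strength_duration_curve> ", x$cell,
      if (nzchar(x$electrode)) paste0(" / ", x$electrode), " (", x$kind,
      ")\n", sep = "")
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' @export
plot.strength_duration_curve <- function(x, ...) {
  graphics::plot(x$points$duration_ms, x$points$threshold_uA, log = "xy",
                 type = "b", pch = 16, xlab = "pulse duration (ms)",
                 ylab = "threshold (uA)",
                 main = paste(x$cell, x$electrode, x$kind), ...)
  invisible(x)
}

#' Weiss strength-duration fit
#'
#' Fits `I_th(PW) = I_rh * (1 + chronaxie / PW)` by linear regression of
#' threshold on `1/PW`.
#'
#' @param curve a [strength_duration()] result.
#' @return list with `rheobase` (uA), `chronaxie` (ms) and `r_squared`.
#' @export
weiss_fit <- function(curve) {
  d <- curve$points
  fit <- lm(threshold_uA ~ I(1 / duration_ms), data = d)
  irh <- coef(fit)[[1L]]
  list(rheobase = irh, chronaxie = coef(fit)[[2L]] / irh,
       r_squared = summary(fit)$r.squared)
}

#' Ratio of two strength-duration curves (e.g. TES1 / TES2)
#'
#' Pointwise division of thresholds at matched durations for the same
#' cell.
#'
#' @param curve_tes1,curve_tes2 [strength_duration()] results on identical
#'   duration grids.
#' @return A `threshold_ratio_curve` data.frame wrapper.
#' @export
threshold_ratio <- function(curve_tes1, curve_tes2) {
  d1 <- curve_tes1$points; d2 <- curve_tes2$points
  if (!isTRUE(all.equal(d1$duration_ms, d2$duration_ms)))
    stop("duration grids do not match")
  if (!identical(curve_tes1$cell, curve_tes2$cell))
    stop("curves belong to different cells")
  structure(list(points = data.frame(duration_ms = d1$duration_ms,
                                     ratio = d1$threshold_uA / d2$threshold_uA),
                 cell = curve_tes1$cell,
                 numerator = curve_tes1$electrode,
                 denominator = curve_tes2$electrode),
            class = "threshold_ratio_curve")
}

#' @method print threshold_ratio_curve
#' @export
print.threshold_ratio_curve <- function(x, ...) {
  cat("<threshold_ratio_curve> ", x$cell, ": ", x$numerator, " / ",
      x$denominator, "\n", sep = "")
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' @export
plot.threshold_ratio_curve <- function(x, ...) {
  graphics::plot(x$points$duration_ms, x$points$ratio, log = "xy",
                 type = "b", pch = 16, xlab = "pulse duration (ms)",
                 ylab = paste0("threshold ratio ", x$numerator, "/",
                               x$denominator),
                 main = x$cell, ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Write a curve as CSV
#' @param curve a strength-duration or ratio curve.
#' @param path output path.
#' @export
write_curve <- function(curve, path) {
  df <- curve$points
  df$cell <- curve$cell
  if (inherits(curve, "strength_duration_curve")) {
    df$electrode <- curve$electrode
    df$kind <- curve$kind
  } else {
    df$numerator <- curve$numerator
    df$denominator <- curve$denominator
  }
  # fixed 9-significant-digit formatting for reproducible output
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 9))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Passive twin of a cell
#'
#' Same morphology, passive properties and leak, with every voltage-gated
#' (and calcium-dependent) conductance removed. Used for linear stimulus
#' artifact subtraction in [find_threshold()] and as the passive reference
#' in cable tests.
#'
#' @param cell a `cable_cell`.
#' @export
passive_twin <- function(cell) {
  dens <- cell$densities
  dens[rownames(dens) != "leak", ] <- 0
  cell$densities <- dens
  cell$state <- NULL
  cell
}
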