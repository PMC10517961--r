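#' Stimulus waveforms
#'
#' A `waveform` is a list of piecewise-constant segments (duration in ms,
#' dimensionless current multiplier) plus an amplitude scale in uA.
#' Cathodic current at the stimulating electrode is negative. Segment
#' bookkeeping is exact (sums of duration x multiplier), so charge balance
#' of biphasic pulses holds to machine precision.
#'
#' @param segments data.frame with columns `duration` (ms, > 0) and
#'   `multiplier` (dimensionless).
#' @param amplitude amplitude scale in uA.
#' @return object of class `waveform`.
#' @export
waveform <- function(segments, amplitude = 1) {
  stopifnot(is.data.frame(segments),
            all(c("duration", "multiplier") %in% names(segments)))
  if (any(segments$duration <= 0)) stop("segment durations must be > 0")
  structure(list(segments = segments, amplitude = amplitude),
            class = "waveform")
}

#' @method print waveform
#' @export
print.waveform <- function(x, ...) {
  cat("<waveform> ", nrow(x$segments), " segments, ",
      format(waveform_span(x)), " ms, amplitude ", x$amplitude, " uA",
      if (is_charge_balanced(x)) ", charge-balanced" else "", "\n", sep = "")
  invisible(x)
}

#' Total span (ms), net charge (uC) and charge balance of a waveform
#' @param w a [waveform()].
#' @export
waveform_span <- function(w) sum(w$segments$duration)

#' @rdname waveform_span
#' @export
waveform_charge <- function(w)
  w$amplitude * sum(w$segments$duration * w$segments$multiplier) / 1e3

#' @rdname waveform_span
#' @export
is_charge_balanced <- function(w)
  sum(w$segments$duration * w$segments$multiplier) == 0

#' Symmetric charge-balanced biphasic pulse
#'
#' Two equal-duration opposite phases (cathodic first by default) with an
#' optional interphase gap; net charge is exactly zero.
#'
#' @param amplitude phase amplitude, uA (> 0).
#' @param phase_duration duration of each phase, ms. Values outside the
#'   0.1-25 ms range raise a warning but are allowed.
#' @param interphase_gap zero-current gap between the phases, ms.
#' @param cathodic_first logical; `FALSE` mirrors the polarity.
#' @export
biphasic_pulse <- function(amplitude, phase_duration, interphase_gap = 0,
                           cathodic_first = TRUE) {
  if (phase_duration <= 0) stop("phase duration must be > 0")
  if (amplitude <= 0) stop("amplitude must be > 0")
  if (phase_duration < 0.1 || phase_duration > 25)
    warning("phase duration ", phase_duration,
            " ms is outside the modelled 0.1-25 ms range")
  s1 <- if (cathodic_first) -1 else 1
  seg <- data.frame(duration = c(phase_duration, phase_duration),
                    multiplier = c(s1, -s1))
  if (interphase_gap > 0)
    seg <- rbind(seg[1L, ],
                 data.frame(duration = interphase_gap, multiplier = 0),
                 seg[2L, ])
  waveform(seg, amplitude)
}

#' Monophasic rectangular pulse
#'
#' @param amplitude amplitude, uA (> 0).
#' @param duration pulse duration, ms.
#' @param polarity `"cathodic"` (negative) or `"anodic"`.
#' @export
monophasic_pulse <- function(amplitude, duration,
                             polarity = c("cathodic", "anodic")) {
  polarity <- match.arg(polarity)
  if (duration <= 0) stop("duration must be > 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (duration < 0.1 || duration > 25)
    warning("duration ", duration,
            " ms is outside the modelled 0.1-25 ms range")
  waveform(data.frame(duration = duration,
                      multiplier = if (polarity == "cathodic") -1 else 1),
           amplitude)
}

#' Fixed-frequency pulse train
#'
#' Repeats `base` at period `1/frequency` with zero fill between pulses.
#'
#' @param base a [waveform()].
#' @param frequency repetition rate, Hz.
#' @param count number of pulses (>= 1).
#' @export
pulse_train <- function(base, frequency, count) {
  stopifnot(inherits(base, "waveform"), frequency > 0, count >= 1)
  count <- as.integer(count)
  if (count == 1L) return(base)
  period <- 1000 / frequency  # ms
  span <- waveform_span(base)
  if (period < span)
    stop("pulses overlap: period ", period, " ms < pulse span ", span, " ms")
  gap <- period - span
  seg <- base$segments
  out <- seg
  for (k in seq_len(count - 1L)) {
    if (gap > 0)
      out <- rbind(out, data.frame(duration = gap, multiplier = 0))
    out <- rbind(out, seg)
  }
  waveform(out, base$amplitude)
}

#' Sample a waveform onto a regular time grid
#'
#' Returns the signed current in uA at times `0, dt, ..., n*dt`. Sample
#' `k` carries the segment covering the interval `((k-1)*dt, k*dt]`, the
#' convention used by the implicit cable step, so per-phase charge is
#' conserved exactly whenever `dt` divides the segment durations. Sample 0
#' and samples after the waveform ends are zero.
#'
#' @param w a [waveform()].
#' @param dt timestep, ms.
#' @param n number of steps (samples are `n + 1`).
#' @export
sample_waveform <- function(w, dt, n) {
  edges <- cumsum(c(0, w$segments$duration))
  t <- (0:n) * dt
  idx <- findInterval(t, edges, left.open = TRUE)
  mult <- numeric(length(t))
  ok <- idx >= 1L & idx <= nrow(w$segments)
  mult[ok] <- w$segments$multiplier[idx[ok]]
  w$amplitude * mult
}

#' Write the sampled waveform as CSV
#' @param w a [waveform()].
#' @param path output path.
#' @param dt sampling step, ms.
#' @export
write_waveform <- function(w, path, dt = 0.01) {
  n <- ceiling(waveform_span(w) / dt)
  df <- data.frame(time_ms = (0:n) * dt,
                   current_uA = sample_waveform(w, dt, n))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
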