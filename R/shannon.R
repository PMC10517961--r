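#' Geometric surface area of a ring (torus) electrode
#'
#' Full torus surface `4 pi^2 R r` with major radius
#' `R = (inner_diameter + wire_diameter) / 2` (the wire centreline) and
#' minor radius `r = wire_diameter / 2`, scaled by the fraction of the wire
#' surface assumed to contact tissue.
#'
#' @param inner_diameter ring inner diameter, mm.
#' @param wire_diameter wire diameter, mm.
#' @param contact_fraction fraction of the torus surface in contact, (0, 1].
#' @return Area in cm^2.
#' @export
ring_electrode_area <- function(inner_diameter, wire_diameter,
                                contact_fraction = 1) {
  if (inner_diameter <= 0 || wire_diameter <= 0)
    stop("electrode dimensions must be > 0")
  if (contact_fraction <= 0 || contact_fraction > 1)
    stop("contact_fraction must lie in (0, 1]")
  R_cm <- (inner_diameter + wire_diameter) / 2 / 10
  r_cm <- wire_diameter / 2 / 10
  4 * pi^2 * R_cm * r_cm * contact_fraction
}

#' Shannon safety point for one stimulus setting
#'
#' Charge per phase `Q = I x t` (uC), charge density per phase
#' `D = Q / area` (uC/cm^2), and the Shannon parameter
#' `k = log10(D) + log10(Q)`; the empirical damage boundary is
#' `log10(D) = k - log10(Q)`.
#'
#' @param amplitude current amplitude, uA.
#' @param phase_duration phase duration, ms.
#' @param area electrode area, cm^2 (see [ring_electrode_area()]).
#' @return list of class `shannon_point` with `amplitude_uA`,
#'   `phase_ms`, `Q_uC`, `D_uC_cm2`, `k`.
#' @export
shannon_point <- function(amplitude, phase_duration, area) {
  if (amplitude <= 0 || phase_duration <= 0 || area <= 0)
    stop("amplitude, phase duration and area must be > 0")
  Q <- amplitude * phase_duration / 1e3  # uA * ms -> uC
  D <- Q / area
  structure(list(amplitude_uA = amplitude, phase_ms = phase_duration,
                 Q_uC = Q, D_uC_cm2 = D, k = log10(D) + log10(Q)),
            class = "shannon_point")
}

#' @method print shannon_point
#' @export
print.shannon_point <- function(x, ...) {
  cat(sprintf("<shannon_point> %g uA x %g ms: Q = %.4g uC, D = %.4g uC/cm^2, k = %.3f\n",
              x$amplitude_uA, x$phase_ms, x$Q_uC, x$D_uC_cm2, x$k))
  invisible(x)
}

#' Shannon chart for a set of amplitudes
#'
#' @param amplitudes amplitudes, uA; default the modelled 20-400 uA grid.
#' @param phase_duration phase duration, ms.
#' @param area electrode area, cm^2.
#' @return data.frame (class `shannon_chart`) with columns `amplitude_uA`,
#'   `Q_uC`, `D_uC_cm2`, `k`.
#' @export
shannon_chart <- function(amplitudes = c(20, 50, 100, 200, 300, 400),
                          phase_duration = 10,
                          area = ring_electrode_area(3, 0.27)) {
  rows <- lapply(amplitudes, shannon_point, phase_duration = phase_duration,
                 area = area)
  df <- data.frame(amplitude_uA = amplitudes,
                   Q_uC = vapply(rows, `[[`, 0, "Q_uC"),
                   D_uC_cm2 = vapply(rows, `[[`, 0, "D_uC_cm2"),
                   k = vapply(rows, `[[`, 0, "k"))
  class(df) <- c("shannon_chart", "data.frame")
  attr(df, "phase_ms") <- phase_duration
  attr(df, "area_cm2") <- area
  df
}

#' @export
plot.shannon_chart <- function(x, k_lines = c(1.5, 2), ...) {
  graphics::plot(x$Q_uC, x$D_uC_cm2, log = "xy", pch = 16,
                 xlab = "charge per phase Q (uC)",
                 ylab = "charge density per phase D (uC/cm^2)", ...)
  qr <- range(x$Q_uC)
  qq <- exp(seq(log(qr[1L] / 2), log(qr[2L] * 2), length.out = 50))
  for (k in k_lines)
    graphics::lines(qq, 10^(k - log10(qq)), lty = 2)
  invisible(x)
}

#' Largest safe amplitude under a Shannon limit
#'
#' The largest tested amplitude whose Shannon `k` stays at or below
#' `k_limit` (default 1.5, the boundary below which no tissue damage is
#' observed).
#'
#' @param amplitudes candidate amplitudes, uA (non-empty).
#' @param phase_duration phase duration, ms.
#' @param area electrode area, cm^2.
#' @param k_limit Shannon damage parameter limit.
#' @return Amplitude in uA.
#' @export
max_safe_amplitude <- function(amplitudes = c(20, 50, 100, 200, 300, 400),
                               phase_duration = 10,
                               area = ring_electrode_area(3, 0.27),
                               k_limit = 1.5) {
  if (!length(amplitudes)) stop("amplitude list is empty")
  k <- vapply(amplitudes, function(a)
    shannon_point(a, phase_duration, area)$k, 0)
  ok <- amplitudes[k <= k_limit]
  if (!length(ok))
    stop("no safe amplitude: every tested amplitude exceeds k = ", k_limit)
  max(ok)
}
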