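#' DC extraction via the lower envelope of a mixed PPG
#'
#' The DC of a mixed PPG is the light transmitted through the non-pulsatile
#' tissue, traced by the lower envelope of the signal. The series is median
#' prefiltered (3 samples), strict local minima are located, minima closer
#' than a minimum spacing (a quarter of the maternal cardiac period, to skip
#' noise dimples) are thinned keeping the lower one, and the retained minima
#' are linearly interpolated onto the full grid with constant extension at
#' the ends. If fewer than two minima exist (e.g. monotone input) the global
#' minimum is used as a constant envelope and the result is flagged.
#'
#' @param x numeric PPG series.
#' @param fs sampling rate, Hz.
#' @param min_spacing_s minimum spacing between retained minima, s; default a
#'   quarter period of a 1.3 Hz maternal heart rate.
#' @param median_k median prefilter width (odd).
#' @return numeric DC series, same length as `x`; attribute `fallback` is
#'   `TRUE` when the constant-envelope fallback was taken.
#' @export
extract_dc <- function(x, fs, min_spacing_s = 0.25 / 1.3, median_k = 3) {
  stopifnot(is.numeric(x), fs > 0)
  n <- length(x)
  xf <- if (n > median_k) stats::runmed(x, median_k) else x
  cand <- local_minima(xf)
  keep <- integer(0)
  spacing <- min_spacing_s * fs
  for (i in cand) {
    if (length(keep) == 0 || i - keep[length(keep)] >= spacing) {
      keep <- c(keep, i)
    } else if (xf[i] < xf[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  if (length(keep) < 2) {
    dc <- rep(min(x), n)
    attr(dc, "fallback") <- TRUE
    return(dc)
  }
  dc <- interp1(keep, xf[keep], seq_len(n))
  attr(dc, "fallback") <- FALSE
  dc
}

#' Variable-frequency quadrature reference from an FHR trace
#'
#' Integrates the instantaneous fetal heart rate into a phase,
#' `phi(t) = 2*pi * integral of fhr`, with the trace linearly interpolated to
#' the output grid, and returns the unit-amplitude quadrature pair
#' `(sin phi, cos phi)` used as lock-in reference.
#'
#' @param trace data.frame with columns `t` (s) and `fhr_hz` (Hz).
#' @param t_grid output time grid, s; must be covered by the trace.
#' @param max_gap largest tolerated gap between trace samples, s.
#' @return list with `t`, `phase`, `sin`, `cos`.
#' @export
build_reference <- function(trace, t_grid, max_gap = 5) {
  if (!all(c("t", "fhr_hz") %in% names(trace)))
    stop("FHR trace needs columns t and fhr_hz")
  if (any(trace$fhr_hz <= 0.5) || any(trace$fhr_hz >= 5))
    stop("FHR values outside the physiological band (0.5, 5) Hz")
  if (min(t_grid) < min(trace$t) - max_gap || max(t_grid) > max(trace$t) + max_gap)
    stop("FHR trace does not cover the requested time grid")
  gaps <- diff(trace$t)
  if (any(gaps > max_gap)) {
    i <- which.max(gaps)
    stop(sprintf("FHR trace gap of %.1f s starting at t = %.1f s exceeds the %g s limit",
                 gaps[i], trace$t[i], max_gap))
  }
  f <- interp1(trace$t, trace$fhr_hz, t_grid)
  phase <- 2 * pi * cumtrapz(t_grid, f)
  list(t = t_grid, phase = phase, sin = sin(phase), cos = cos(phase))
}

#' Lock-in AC magnitude at the (time-varying) fetal heart rate
#'
#' Mixes the PPG with the quadrature reference, low-pass filters both
#' products (zero-phase Butterworth), and returns
#' `ac = 2 * sqrt(I^2 + Q^2)`; the factor 2 restores the amplitude of a
#' sinusoidal component at the reference frequency. The result is invariant
#' to the phase of that component.
#'
#' @param x numeric PPG series.
#' @param reference output of [build_reference()] on the same grid.
#' @param fs sampling rate, Hz.
#' @param cutoff lock-in low-pass cutoff, Hz. The default 0.15 Hz rejects the
#'   maternal cardiac line (>= 0.6 Hz away from the FHR in these experiments)
#'   while following the slow drift of the fetal amplitude.
#' @param order Butterworth order.
#' @return non-negative AC magnitude series, same length as `x`.
#' @export
lockin_ac <- function(x, reference, fs, cutoff = 0.15, order = 4) {
  if (length(x) != length(reference$sin))
    stop("signal and reference length mismatch")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  i <- filtfilt_pad(bf, x * reference$sin)
  q <- filtfilt_pad(bf, x * reference$cos)
  2 * sqrt(i^2 + q^2)
}

#' AC and DC series for every detector and wavelength
#'
#' Applies [extract_dc()] and [lockin_ac()] to each channel of a
#' [demodulate_recording()] output.
#'
#' @param ppg a `wavelength_ppg`.
#' @param trace FHR trace (data.frame `t`, `fhr_hz`).
#' @param ... forwarded to [lockin_ac()].
#' @return object of class `acdc_series`: `ac[[d]][[wavelength]]`,
#'   `dc[[d]][[wavelength]]`, plus `fs`, `t`, `wavelengths`.
#' @export
extract_acdc <- function(ppg, trace, ...) {
  stopifnot(inherits(ppg, "wavelength_ppg"))
  n <- length(ppg$power[[1]][[1]])
  t_grid <- (0:(n - 1)) / ppg$fs
  ref <- build_reference(trace, t_grid)
  ac <- dc <- vector("list", length(ppg$power))
  for (d in seq_along(ppg$power)) {
    ac[[d]] <- lapply(ppg$power[[d]], lockin_ac, reference = ref, fs = ppg$fs, ...)
    dc[[d]] <- lapply(ppg$power[[d]], extract_dc, fs = ppg$fs)
  }
  structure(list(ac = ac, dc = dc, fs = ppg$fs, t = t_grid,
                 wavelengths = ppg$wavelengths),
            class = "acdc_series")
}

#' @export
print.acdc_series <- function(x, ...) {
  cat(sprintf("AC/DC series: %d detectors x {%s} nm, %.1f s at %g Hz\n",
              length(x$ac), paste(x$wavelengths, collapse = ", "),
              length(x$t) / x$fs, x$fs))
  invisible(x)
}
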