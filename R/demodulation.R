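#' Demodulate a raw multiplexed recording into per-wavelength envelopes
#'
#' Each detector output carries both LEDs' light, distinguishable only by
#' their on/off toggle frequencies. Synchronous (quadrature lock-in)
#' detection against the fundamental of each square wave recovers the
#' wavelength-specific envelope: the raw signal is mixed with `2*sin` and
#' `2*cos` at the toggle frequency, both products are low-pass filtered
#' (zero-phase Butterworth), and the quadrature magnitude is rescaled by
#' `pi/2` to undo the `2/pi` fundamental amplitude of a 50%-duty square wave.
#' Quadrature detection makes the result independent of the unknown toggle
#' phase.
#'
#' @param raw a `tfo_recording`.
#' @param cutoff low-pass cutoff, Hz; must leave the envelope band intact
#'   while rejecting inter-LED mixing products.
#' @param order Butterworth order.
#' @return list of per-detector lists of per-wavelength numeric envelope
#'   series, still at `fs_raw`; attributes `fs` and `wavelengths`.
#' @export
demodulate <- function(raw, cutoff = 20, order = 4) {
  stopifnot(inherits(raw, "tfo_recording"))
  fs <- raw$fs_raw
  freqs <- raw$mod_freqs
  if (length(freqs) < 1 || is.null(names(freqs)))
    stop("recording must carry named modulation frequencies")
  if (min(abs(diff(sort(freqs)))) <= 2 * cutoff)
    warning("modulation frequencies closer than twice the demodulation cutoff: envelopes may leak")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  n <- length(raw$signals[[1]])
  tt <- (0:(n - 1)) / fs
  refs <- lapply(names(freqs), function(w) {
    ph <- 2 * pi * freqs[[w]] * tt
    list(s = 2 * sin(ph), c = 2 * cos(ph))
  })
  names(refs) <- names(freqs)
  out <- lapply(raw$signals, function(x) {
    env <- lapply(names(freqs), function(w) {
      i <- filtfilt_pad(bf, x * refs[[w]]$s)
      q <- filtfilt_pad(bf, x * refs[[w]]$c)
      (pi / 2) * sqrt(i^2 + q^2)
    })
    names(env) <- names(freqs)
    env
  })
  attr(out, "fs") <- fs
  attr(out, "wavelengths") <- names(freqs)
  out
}

# one decimate-by-q stage: Chebyshev-I (order 8, 0.05 dB ripple) anti-alias
# at 0.8 * new Nyquist, applied zero-phase, then every q-th sample.
# even-order Chebyshev-I sits at -rp dB at DC; rescale so DC gain is exactly 1
decimate_stage <- function(x, q) {
  cf <- signal::cheby1(8, 0.05, 0.8 / q, type = "low")
  dc_gain <- sum(cf$b) / sum(cf$a)
  y <- filtfilt_pad(cf, x) / dc_gain^2
  y[seq(1, length(x), by = q)]
}

#' Anti-aliased downsampling of a demodulated series
#'
#' Decimates by `factor` (default 100: 8 kHz to 80 Hz) using cascaded
#' Chebyshev-I stages of at most 10x each, applied zero-phase. The passband
#' is flat to within 0.1 dB below a quarter of the output Nyquist rate, which
#' covers the fetal heart-rate band and its first harmonics.
#'
#' @param x numeric series.
#' @param factor overall decimation factor (positive integer; factors of 10
#'   are peeled off first).
#' @return decimated series of length `ceiling(length(x)/factor)`.
#' @export
downsample_ppg <- function(x, factor = 100) {
  stopifnot(is.numeric(x), factor >= 1, factor == round(factor))
  if (length(x) < factor) stop("series shorter than one decimation block")
  q <- factor
  while (q > 1) {
    step <- if (q %% 10 == 0) 10 else q
    x <- decimate_stage(x, step)
    q <- q / step
  }
  x
}

#' Convert a detected envelope to source-normalized optical power
#'
#' Divides out the detector gain, LED drive current, and an optional device
#' constant, so recordings taken at different instrument settings become
#' directly comparable.
#'
#' @param x numeric envelope series.
#' @param gain detector gain (> 0).
#' @param led_current LED drive current (> 0).
#' @param device_constant radiometric calibration constant (> 0, default 1).
#' @return normalized series.
#' @export
source_normalize <- function(x, gain, led_current, device_constant = 1) {
  if (!is.finite(gain) || gain <= 0) stop("gain must be strictly positive")
  if (!is.finite(led_current) || led_current <= 0)
    stop("led_current must be strictly positive")
  if (!is.finite(device_constant) || device_constant <= 0)
    stop("device_constant must be strictly positive")
  x / (gain * led_current * device_constant)
}

#' Full front end: raw recording to source-normalized 80 Hz wavelength PPGs
#'
#' Synchronous detection and rate reduction fused into one pass: the raw
#' signal is mixed with the quadrature pair at each toggle frequency, both
#' products go straight through the anti-aliased decimation chain (whose
#' low-pass doubles as the lock-in filter), and the quadrature magnitude is
#' formed at the output rate before source normalization. Numerically
#' equivalent to [demodulate()] + [downsample_ppg()] for envelopes inside
#' the decimator passband, at a fraction of the cost.
#'
#' @param raw a `tfo_recording`.
#' @param fs_out output sampling rate, Hz.
#' @param device_constant forwarded to [source_normalize()].
#' @return object of class `wavelength_ppg`: `power[[d]][[wavelength]]`
#'   series at `fs_out`, plus `fs`, `wavelengths`, `distances`.
#' @export
demodulate_recording <- function(raw, fs_out = 80, device_constant = 1) {
  stopifnot(inherits(raw, "tfo_recording"))
  fs <- raw$fs_raw
  factor <- fs / fs_out
  if (factor != round(factor)) stop("fs_raw must be an integer multiple of fs_out")
  n <- length(raw$signals[[1]])
  tt <- (0:(n - 1)) / fs
  refs <- lapply(names(raw$mod_freqs), function(w) {
    ph <- 2 * pi * raw$mod_freqs[[w]] * tt
    list(s = 2 * sin(ph), c = 2 * cos(ph))
  })
  names(refs) <- names(raw$mod_freqs)
  # the 20 Hz lock-in low-pass runs at the intermediate rate, where it is
  # cheap; it removes aliased square-harmonic beats (e.g. the 13th harmonic
  # of 690 Hz aliasing to 970 Hz, beating the 940 Hz reference at 30 Hz)
  # that the anti-alias chain alone would pass
  mid_q <- if (factor %% 10 == 0) 10 else factor
  bf_mid <- signal::butter(4, 20 / (fs / mid_q / 2), type = "low")
  reduce <- function(v) {
    v <- decimate_stage(v, mid_q)
    v <- filtfilt_pad(bf_mid, v)
    if (factor > mid_q) v <- downsample_ppg(v, factor / mid_q)
    v
  }
  power <- lapply(seq_along(raw$signals), function(d) {
    x <- raw$signals[[d]]
    p <- lapply(names(raw$mod_freqs), function(w) {
      i <- reduce(x * refs[[w]]$s)
      q <- reduce(x * refs[[w]]$c)
      env <- (pi / 2) * sqrt(i^2 + q^2)
      source_normalize(env, raw$gains[d], raw$led_currents[[w]], device_constant)
    })
    names(p) <- names(raw$mod_freqs)
    p
  })
  structure(list(power = power, fs = fs_out,
                 wavelengths = names(raw$mod_freqs),
                 distances = raw$distances),
            class = "wavelength_ppg")
}

#' @export
print.wavelength_ppg <- function(x, ...) {
  cat(sprintf("Wavelength PPG: %d detectors x {%s} nm, %.1f s at %g Hz\n",
              length(x$power), paste(x$wavelengths, collapse = ", "),
              length(x$power[[1]][[1]]) / x$fs, x$fs))
  invisible(x)
}
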