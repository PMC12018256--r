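#' Synthesize a raw multiplexed detector recording
#'
#' Builds the raw 8 ksps output of every detector. For detector d and
#' wavelength lambda the pre-modulation optical power is
#' `P = base_power[d, lambda] * (1 + maternal + respiratory + fetal)` where the
#' maternal term is a sinusoid at the instantaneous maternal heart rate, the
#' respiratory term holds the ventilator fundamental plus harmonics, and the
#' fetal term is a sinusoid at the instantaneous fetal heart rate whose
#' relative amplitude is the small-signal intensity change
#' `ln(10) * dA(lambda, S(t)) * fetal_fraction[d]` implied by the modified
#' Beer-Lambert forward model. Each wavelength's power is multiplied by its
#' 50%-duty LED on/off square wave and the two are summed at the (color-blind)
#' detector, scaled by gain and LED current, plus Gaussian noise. By
#' construction the ratio of the two wavelengths' fetal AC/DC equals
#' `phi_from_state` of the instantaneous saturation.
#'
#' @param config a [sim_config()].
#' @param truth matching [generate_truth()] output.
#' @return object of class `tfo_recording`: list with `signals` (list of
#'   numeric vectors at `fs_raw`), `fs_raw`, `mod_freqs`, `gains`,
#'   `led_currents`, `distances`, `t0`.
#' @export
synthesize_recording <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "tfo_truth"))
  if (truth$round_duration < config$round_duration)
    stop("truth does not cover the configured round duration")
  fs <- config$fs_raw
  n <- as.integer(config$round_duration * fs)
  t8 <- (0:(n - 1)) / fs
  with_seed(config$seed + 1L, {
    # shared low-rate components interpolated to the raw grid
    mhr_hz <- interp1(truth$t, truth$mhr / 60, t8)
    phase_m <- 2 * pi * cumsum(mhr_hz) / fs
    rm(mhr_hz)
    maternal <- config$maternal_pulsation * sin(phase_m)
    rm(phase_m)
    resp <- 0
    for (k in seq_len(config$resp_harmonics))
      resp <- resp + (config$resp_amplitude / k) * sin(2 * pi * k * config$mrr * t8)
    common <- 1 + maternal + resp
    rm(maternal, resp)
    fhr_hz <- interp1(truth$t, truth$fhr / 60, t8)
    sin_f <- sin(2 * pi * cumsum(fhr_hz) / fs)
    rm(fhr_hz)
    s8 <- interp1(truth$t, truth$fsao2, t8) / 100
    # per-wavelength fetal modulation before the detector-specific fraction
    fet <- lapply(config$wavelengths, function(w) {
      da <- delta_absorbance(chromophore_state(s8, config$fetal_delta_c,
                                               config$mean_path),
                             config$eps, as.numeric(w))
      log(10) * da * sin_f
    })
    names(fet) <- config$wavelengths
    rm(s8, sin_f)
    # 50%-duty 0/1 square waves at the LED toggle rates, band-limited below
    # the raw Nyquist rate (the acquisition front end's anti-alias filter
    # removes harmonics that would otherwise fold onto the 10 Hz
    # intermodulation grid of the two toggle frequencies)
    sq <- lapply(config$wavelengths, function(w) {
      f <- config$mod_freqs[[w]]
      ks <- seq(1, floor((config$fs_raw / 2 - 1) / f), by = 2)
      v <- rep(0.5, n)
      for (k in ks) v <- v + (2 / (pi * k)) * sin(2 * pi * k * f * t8)
      v
    })
    names(sq) <- config$wavelengths
    signals <- vector("list", config$n_detectors)
    for (d in seq_len(config$n_detectors)) {
      sig <- numeric(n)
      for (w in config$wavelengths) {
        p <- config$base_power[d, w] * (common + config$fetal_fraction[d] * fet[[w]])
        sig <- sig + config$led_currents[[w]] * (sq[[w]] * p)
      }
      sig <- config$gains[d] * sig
      if (config$noise_sd > 0) sig <- sig + stats::rnorm(n, 0, config$noise_sd)
      signals[[d]] <- sig
    }
    structure(list(signals = signals, fs_raw = fs, mod_freqs = config$mod_freqs,
                   gains = config$gains, led_currents = config$led_currents,
                   distances = config$distances, t0 = 0),
              class = "tfo_recording")
  })
}

#' @export
print.tfo_recording <- function(x, ...) {
  cat(sprintf(
    "TFO raw recording: %d detectors, %.1f s at %g sps, LED toggles %s Hz\n",
    length(x$signals), length(x$signals[[1]]) / x$fs_raw,
    x$fs_raw, paste(x$mod_freqs, collapse = "/")))
  invisible(x)
}

#' Artifact specification around blood-draw times
#'
#' Default artifact windows mimicking the disturbances observed around blood
#' draws: a baseline step plus a broadband burst in a short window at each
#' ABG draw.
#'
#' @param truth a `tfo_truth`.
#' @param width window width, s.
#' @param step_amplitude baseline shift amplitude (raw signal units).
#' @param burst_sd burst noise s.d. (raw signal units).
#' @return data.frame with columns `t_start`, `t_end`, `type`, `amplitude`.
#' @export
default_artifact_spec <- function(truth, width = 10,
                                  step_amplitude = 0.05, burst_sd = 0.05) {
  stopifnot(inherits(truth, "tfo_truth"))
  tt <- truth$abg$t
  rbind(
    data.frame(t_start = tt, t_end = tt + width, type = "step",
               amplitude = step_amplitude),
    data.frame(t_start = tt, t_end = tt + width, type = "burst",
               amplitude = burst_sd))
}

#' Inject motion / blood-draw artifacts into a raw recording
#'
#' Adds baseline steps, ramps, or broadband noise bursts inside the specified
#' windows, on every detector channel. Samples outside all windows are left
#' bit-identical. Overlapping windows of the same type are merged with a
#' warning.
#'
#' @param recording a `tfo_recording`.
#' @param artifact_spec data.frame with columns `t_start`, `t_end` (s),
#'   `type` (`"step"`, `"ramp"` or `"burst"`) and `amplitude` (step/ramp
#'   height or burst s.d., raw units). `NULL` or empty = unchanged.
#' @param seed RNG seed for burst noise.
#' @return the recording with artifacts added.
#' @export
inject_artifacts <- function(recording, artifact_spec, seed = 1) {
  stopifnot(inherits(recording, "tfo_recording"))
  if (is.null(artifact_spec) || nrow(artifact_spec) == 0) return(recording)
  req <- c("t_start", "t_end", "type", "amplitude")
  if (!all(req %in% names(artifact_spec)))
    stop("artifact_spec needs columns t_start, t_end, type, amplitude")
  fs <- recording$fs_raw
  n <- length(recording$signals[[1]])
  if (any(artifact_spec$t_start < 0) || any(artifact_spec$t_end * fs > n))
    stop("artifact windows must lie within the recording")
  spec <- artifact_spec[order(artifact_spec$t_start), , drop = FALSE]
  merged <- list()
  for (ty in unique(spec$type)) {
    s <- spec[spec$type == ty, , drop = FALSE]
    i <- 1
    while (i <= nrow(s)) {
      j <- i
      while (j < nrow(s) && s$t_start[j + 1] < s$t_end[j]) {
        warning(sprintf("merging overlapping %s artifact windows at %g s", ty,
                        s$t_start[j + 1]))
        j <- j + 1
      }
      merged[[length(merged) + 1]] <-
        data.frame(t_start = s$t_start[i], t_end = max(s$t_end[i:j]),
                   type = ty, amplitude = s$amplitude[i])
      i <- j + 1
    }
  }
  merged <- do.call(rbind, merged)
  with_seed(seed, {
    for (k in seq_len(nrow(merged))) {
      i0 <- max(1L, floor(merged$t_start[k] * fs) + 1L)
      i1 <- min(n, ceiling(merged$t_end[k] * fs))
      idx <- i0:i1
      add <- switch(merged$type[k],
        step = rep(merged$amplitude[k], length(idx)),
        ramp = seq(0, merged$amplitude[k], length.out = length(idx)),
        burst = stats::rnorm(length(idx), 0, merged$amplitude[k]),
        stop(sprintf("unknown artifact type '%s'", merged$type[k])))
      for (d in seq_along(recording$signals))
        recording$signals[[d]][idx] <- recording$signals[[d]][idx] + add
    }
    recording
  })
}
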