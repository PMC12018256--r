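# shared fixtures, all generated in code

# a raw recording built directly from known envelopes (bypasses the simulator)
make_recording <- function(env740, env850, fs = 8000,
                           mod_freqs = c("740" = 690, "850" = 940),
                           gains = 1, led_currents = c("740" = 1, "850" = 1),
                           band_limited = TRUE) {
  n <- length(env740)
  tt <- (0:(n - 1)) / fs
  sq <- lapply(names(mod_freqs), function(w) {
    f <- mod_freqs[[w]]
    if (band_limited) {
      ks <- seq(1, floor((fs / 2 - 1) / f), by = 2)
      v <- rep(0.5, n)
      for (k in ks) v <- v + (2 / (pi * k)) * sin(2 * pi * k * f * tt)
      v
    } else as.numeric((tt * f) %% 1 < 0.5)
  })
  names(sq) <- names(mod_freqs)
  sig <- gains[1] * (led_currents[["740"]] * sq[["740"]] * env740 +
                     led_currents[["850"]] * sq[["850"]] * env850)
  structure(list(signals = list(sig), fs_raw = fs, mod_freqs = mod_freqs,
                 gains = gains, led_currents = led_currents,
                 distances = 1.5, t0 = 0),
            class = "tfo_recording")
}

# small two-detector configuration for fast pipeline runs; any argument
# overrides the fixture defaults
tiny_config <- function(...) {
  defaults <- list(distances = c(1.5, 4.5), fetal_fraction = c(0.05, 0.15),
                   gains = c(1, 1), n_steps = 1, step_duration = 60,
                   fsao2_start = 50, fsao2_end = 50, noise_sd = 0,
                   abg_noise_sd = 0)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# the steady-state region of a filtered series (drops edge transients)
mid_region <- function(x, frac = 0.2) {
  n <- length(x)
  x[max(1, floor(n * frac)):min(n, ceiling(n * (1 - frac)))]
}

expected_fetal_acdc <- function(cfg, s_frac, detector, wavelength) {
  st <- chromophore_state(s_frac, cfg$fetal_delta_c, cfg$mean_path)
  log(10) * delta_absorbance(st, cfg$eps, wavelength) *
    cfg$fetal_fraction[detector]
}
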