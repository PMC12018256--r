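#' Configuration of the synthetic mixed-PPG experiment
#'
#' Defines one simulated hypoxic round of a controlled fetal de-saturation
#' experiment: five photodetectors at increasing distance from a dual-LED
#' source, maternal cardiac and (ventilated, fixed-rate) respiratory
#' components, and a faint fetal pulsatile component whose two-wavelength
#' amplitudes follow the modified Beer-Lambert law as the fetal arterial
#' saturation declines stepwise under progressive aortic balloon occlusion.
#'
#' Received DC power decays exponentially with source-detector distance,
#' while the fraction of detected photons that traversed fetal tissue grows
#' with distance; together these reproduce the characteristic pattern that
#' close detectors see strong signals with little fetal content and far
#' detectors see weak signals with proportionally more fetal pulsation
#' (fetal AC 2-4 orders of magnitude below DC).
#'
#' @param distances source-detector distances, cm.
#' @param fs_raw raw sampling rate, samples/s.
#' @param mod_freqs LED on/off toggle frequencies, Hz, named by wavelength nm.
#' @param n_steps number of occlusion (dMAP) steps in the round.
#' @param step_duration duration of one step, s (blood draws at 2.5/5/10 min
#'   within each 10-min step).
#' @param fsao2_start,fsao2_end fetal arterial saturation, %, at round start
#'   and end; the trajectory declines smoothly within each step.
#' @param mhr_range,fhr_range maternal/fetal heart-rate bounds, bpm.
#' @param mrr maternal (ventilator) respiratory rate, Hz; fixed.
#' @param base_power0 source-normalized received power at zero distance,
#'   per wavelength.
#' @param decay_per_cm exponential attenuation rate per cm, per wavelength.
#' @param fetal_fraction fraction of detected power that traversed fetal
#'   tissue, per detector; non-decreasing with distance.
#' @param maternal_pulsation maternal cardiac AC/DC magnitude.
#' @param resp_amplitude fundamental respiratory AC/DC magnitude.
#' @param resp_harmonics number of respiratory harmonics (>= 2), amplitudes
#'   decaying as 1/k.
#' @param fetal_delta_c pulsatile change in fetal total hemoglobin, mM
#'   (forwarded to the Beer-Lambert forward model).
#' @param mean_path mean photon path length in fetal tissue, cm.
#' @param gains per-detector electronic gain.
#' @param led_currents LED drive currents, named by wavelength.
#' @param noise_sd additive Gaussian noise s.d. on the raw detector output
#'   (same units as the raw signal).
#' @param abg_noise_sd measurement noise s.d. on blood-gas saturation
#'   readings, saturation points.
#' @param fhr_step_sd,mhr_step_sd per-second random-walk step s.d., bpm.
#' @param threshold hypoxemia threshold on fSaO2, %.
#' @param eps extinction table used by the forward model.
#' @param seed RNG seed; the whole round is reproducible given the config.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(distances = c(1.5, 3, 4.5, 7, 10),
                       fs_raw = 8000,
                       mod_freqs = c("740" = 690, "850" = 940),
                       n_steps = 4,
                       step_duration = 600,
                       fsao2_start = 60,
                       fsao2_end = 15,
                       mhr_range = c(75, 84),
                       fhr_range = c(120, 174),
                       mrr = 0.25,
                       base_power0 = c("740" = 1.0, "850" = 1.2),
                       decay_per_cm = c("740" = 1.15, "850" = 1.05),
                       fetal_fraction = c(0.02, 0.05, 0.10, 0.15, 0.20),
                       maternal_pulsation = 0.02,
                       resp_amplitude = 0.01,
                       resp_harmonics = 3,
                       fetal_delta_c = 2e-3,
                       mean_path = 10,
                       gains = rep(1, length(distances)),
                       led_currents = c("740" = 1, "850" = 1),
                       noise_sd = 0,
                       abg_noise_sd = 0.5,
                       fhr_step_sd = 0.5,
                       mhr_step_sd = 0.2,
                       threshold = 30,
                       eps = extinction_table(),
                       seed = 1) {
  nd <- length(distances)
  if (nd < 1 || is.unsorted(distances, strictly = TRUE))
    stop("distances must be strictly increasing")
  if (length(mod_freqs) != 2 || mod_freqs[1] == mod_freqs[2])
    stop("mod_freqs must hold two distinct toggle frequencies")
  if (any(mod_freqs >= fs_raw / 2))
    stop("modulation frequencies must be below the raw Nyquist rate")
  if (n_steps < 1) stop("need at least one hypoxic step")
  if (step_duration <= 0) stop("step_duration must be positive")
  if (length(fetal_fraction) != nd || is.unsorted(fetal_fraction))
    stop("fetal_fraction must be non-decreasing, one value per detector")
  if (any(fetal_fraction < 0 | fetal_fraction > 1))
    stop("fetal_fraction must lie in [0, 1]")
  if (any(c(fsao2_start, fsao2_end) < 0 | c(fsao2_start, fsao2_end) > 100))
    stop("fSaO2 endpoints must lie in [0, 100] %")
  if (resp_harmonics < 2) stop("resp_harmonics must be at least 2")
  if (any(gains <= 0) || any(led_currents <= 0))
    stop("gains and led_currents must be strictly positive")
  wl <- names(mod_freqs)
  if (is.null(wl) || !setequal(wl, as.character(eps$wavelengths)))
    stop("mod_freqs must be named by the extinction-table wavelengths")
  base_power <- sapply(wl, function(w)
    unname(base_power0[w]) * exp(-unname(decay_per_cm[w]) * distances))
  base_power <- matrix(base_power, nrow = nd,
                       dimnames = list(NULL, wl))
  if (nd > 1 && any(apply(base_power, 2, diff) >= 0))
    stop("base power must strictly decrease with detector distance")
  structure(list(
    distances = distances, n_detectors = nd, fs_raw = fs_raw,
    mod_freqs = mod_freqs, wavelengths = wl,
    n_steps = n_steps, step_duration = step_duration,
    round_duration = n_steps * step_duration,
    fsao2_start = fsao2_start, fsao2_end = fsao2_end,
    mhr_range = mhr_range, fhr_range = fhr_range, mrr = mrr,
    base_power = base_power, fetal_fraction = fetal_fraction,
    maternal_pulsation = maternal_pulsation,
    resp_amplitude = resp_amplitude, resp_harmonics = resp_harmonics,
    fetal_delta_c = fetal_delta_c, mean_path = mean_path,
    gains = gains, led_currents = led_currents,
    noise_sd = noise_sd, abg_noise_sd = abg_noise_sd,
    fhr_step_sd = fhr_step_sd, mhr_step_sd = mhr_step_sd,
    threshold = threshold, eps = eps, seed = seed),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic TFO round: %d detectors at {%s} cm, %d x %g s steps\n",
    "  fSaO2 %g%% -> %g%%, MHR %g-%g bpm, FHR %g-%g bpm, MRR %g Hz\n",
    "  fs_raw %g sps, LED toggles %s Hz, noise_sd %g, seed %d\n"),
    x$n_detectors, paste(x$distances, collapse = ", "),
    x$n_steps, x$step_duration,
    x$fsao2_start, x$fsao2_end, x$mhr_range[1], x$mhr_range[2],
    x$fhr_range[1], x$fhr_range[2], x$mrr,
    x$fs_raw, paste(x$mod_freqs, collapse = "/"), x$noise_sd, x$seed))
  invisible(x)
}
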