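#' Generate the ground truth of one simulated hypoxic round
#'
#' Produces the physiological ground truth underlying a synthetic recording:
#' a stepwise-declining fetal arterial saturation trajectory (one step per
#' occlusion stage, smooth linear drift within each step), bounded-random-walk
#' fetal and maternal heart-rate traces at 1 Hz, arterial blood gas (ABG)
#' draws at the 2.5, 5 and 10 min marks of each 10-min step with measurement
#' noise, and hypoxemia labels obtained by linear interpolation of the ABG
#' draws against the saturation threshold (strictly below = hypoxemic), the
#' same labeling rule applied to real experiments.
#'
#' @param config a [sim_config()].
#' @return object of class `tfo_truth` with fields `t`, `fsao2`, `fhr`, `mhr`
#'   (1 Hz vectors; heart rates in bpm, saturation in %), `abg`
#'   (data.frame `t`, `fsao2`), `labels` (logical, `NA` outside the ABG span),
#'   and `threshold`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dur <- config$round_duration
  if (dur < config$step_duration) stop("round shorter than one hypoxic step")
  with_seed(config$seed, {
    t <- 0:(dur - 1)
    # stepwise decline: step s drifts linearly from v[s] to v[s+1]
    v <- seq(config$fsao2_start, config$fsao2_end, length.out = config$n_steps + 1)
    brk <- seq(0, dur, by = config$step_duration)
    fsao2 <- interp1(brk, v, t)
    fhr <- bounded_walk(dur, mean(config$fhr_range), config$fhr_step_sd,
                        config$fhr_range[1], config$fhr_range[2])
    mhr <- bounded_walk(dur, mean(config$mhr_range), config$mhr_step_sd,
                        config$mhr_range[1], config$mhr_range[2])
    draw_offsets <- c(150, 300, 600) * config$step_duration / 600
    abg_t <- as.vector(outer(draw_offsets,
                             config$step_duration * (seq_len(config$n_steps) - 1), "+"))
    abg_t <- sort(abg_t)
    abg_val <- interp1(c(t, dur), c(fsao2, config$fsao2_end), abg_t) +
      stats::rnorm(length(abg_t), 0, config$abg_noise_sd)
    abg_val <- pmin(pmax(abg_val, 0), 100)
    abg <- data.frame(t = abg_t, fsao2 = abg_val)
    labels <- label_samples(abg, t, threshold = config$threshold)
    structure(list(t = t, fsao2 = fsao2, fhr = fhr, mhr = mhr,
                   abg = abg, labels = labels, threshold = config$threshold,
                   round_duration = dur),
              class = "tfo_truth")
  })
}

#' @export
print.tfo_truth <- function(x, ...) {
  cat(sprintf(
    "TFO ground truth: %g s round, fSaO2 %.1f%% -> %.1f%%, %d ABG draws, %d/%d hypoxemic s\n",
    x$round_duration, x$fsao2[1], x$fsao2[length(x$fsao2)], nrow(x$abg),
    sum(x$labels, na.rm = TRUE), sum(!is.na(x$labels))))
  invisible(x)
}

#' Fetal heart-rate reference trace from ground truth
#'
#' Extracts the FHR trace in the form consumed by [build_reference()]
#' (mirroring the carotid-line hemodynamic reference of the experiments).
#'
#' @param truth a `tfo_truth`.
#' @return data.frame with columns `t` (s) and `fhr_hz`.
#' @export
fhr_trace <- function(truth) {
  stopifnot(inherits(truth, "tfo_truth"))
  data.frame(t = truth$t, fhr_hz = truth$fhr / 60)
}
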