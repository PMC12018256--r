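#' Simulate a multi-round feature-level cohort
#'
#' Generates a cohort of hypoxic rounds directly at the feature level,
#' bypassing the raw 8 kHz synthesis: for each round a ground-truth
#' saturation trajectory and ABG draws are generated with
#' [generate_truth()], the per-detector instantaneous modulation ratio is
#' the Beer-Lambert value `phi_from_state(S(t))` scaled by a round- and
#' detector-specific sensitivity (emulating fetal depth / probe-placement
#' variability), pulsation ratios sit at round-specific levels that grow
#' with detector distance, multiplicative noise is added, and the standard
#' post-processing (outlier rejection, 1.5-min smoothing, ABG labeling)
#' produces the 1 Hz feature table. This is the cohort scale at which the
#' classifier and cross-validation harness are exercised.
#'
#' The default profiles mirror the composition of the animal experiments:
#' a mix of rounds starting normoxemic (35-60%) that descend through the
#' 30% threshold, and rounds that are hypoxemic throughout (15-30% down).
#'
#' @param profiles list of `c(fsao2_start, fsao2_end)` per round, %.
#' @param round_minutes round durations, min (recycled).
#' @param n_detectors number of detectors.
#' @param phi_noise_sd multiplicative noise s.d. on the instantaneous
#'   modulation ratio.
#' @param pr_noise_sd multiplicative noise s.d. on the pulsation ratios.
#' @param sensitivity_sd s.d. of the log-normal round/detector sensitivity.
#' @param fs feature-level simulation rate, Hz (1 Hz: the smoother's input
#'   grid).
#' @param window smoothing window, s.
#' @param threshold hypoxemia threshold, %.
#' @param eps extinction table for the forward model.
#' @param seed RNG seed.
#' @return a `tfo_features` table over all rounds, plus attribute `truths`.
#' @export
simulate_feature_cohort <- function(profiles = list(c(55, 18), c(45, 12),
                                                    c(60, 20), c(28, 10),
                                                    c(25, 8)),
                                    round_minutes = c(40, 30, 40, 30, 20),
                                    n_detectors = 5,
                                    phi_noise_sd = 0.2,
                                    pr_noise_sd = 0.2,
                                    sensitivity_sd = 0.3,
                                    fs = 1,
                                    window = 90,
                                    threshold = 30,
                                    eps = extinction_table(),
                                    seed = 1) {
  round_minutes <- rep_len(round_minutes, length(profiles))
  out <- vector("list", length(profiles))
  truths <- vector("list", length(profiles))
  for (r in seq_along(profiles)) {
    dur <- round_minutes[r] * 60
    n_steps <- max(1, round(dur / 600))
    cfg <- sim_config(n_steps = n_steps, step_duration = dur / n_steps,
                      fsao2_start = profiles[[r]][1],
                      fsao2_end = profiles[[r]][2],
                      threshold = threshold, eps = eps,
                      seed = seed + 1000L * r)
    truth <- generate_truth(cfg)
    truths[[r]] <- truth
    out[[r]] <- with_seed(seed + 1000L * r + 1L, {
      t <- seq(0, dur - 1, by = 1 / fs)
      s_frac <- interp1(truth$t, truth$fsao2, t) / 100
      phi_true <- phi_from_state(chromophore_state(s_frac), eps)
      sens <- exp(stats::rnorm(n_detectors, 0, sensitivity_sd))
      # pulsation levels grow with detector distance, jittered per round
      pr_level <- 10^seq(-3.5, -2, length.out = n_detectors) *
        exp(stats::rnorm(n_detectors, 0, sensitivity_sd))
      t_out <- seq(ceiling(min(t)), floor(max(t)), by = 1)
      pr_cols <- list(); phi_cols <- list()
      for (d in seq_len(n_detectors)) {
        phi_inst <- phi_true * sens[d] *
          exp(stats::rnorm(length(t), 0, phi_noise_sd))
        pr850 <- pr_level[d] * exp(stats::rnorm(length(t), 0, pr_noise_sd))
        pr740 <- pr850 * phi_inst
        pr_cols[[sprintf("pr_d%d_740", d)]] <-
          window_mean_1hz(t, pr740, t_out, window / 2)
        pr_cols[[sprintf("pr_d%d_850", d)]] <-
          window_mean_1hz(t, pr850, t_out, window / 2)
        phi_cols[[sprintf("phi_d%d", d)]] <-
          reject_and_smooth(t, phi_inst, t_out, window = window)$phi
      }
      pulsation <- as.matrix(as.data.frame(pr_cols))
      modulation <- as.matrix(as.data.frame(phi_cols))
      labels <- label_samples(truth$abg, t_out, threshold)
      assemble_samples(pulsation, modulation, labels, t_out,
                       round_id = r, window = window)
    })
  }
  res <- do.call(rbind, out)
  class(res) <- c("tfo_features", "data.frame")
  attr(res, "truths") <- truths
  res
}
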