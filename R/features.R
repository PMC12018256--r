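#' Pulsation ratio (AC/DC) of one channel
#'
#' Pointwise ratio of the fetal AC magnitude to the DC envelope. Samples with
#' a non-positive DC are marked invalid (`NA`) rather than raising an error.
#'
#' @param ac,dc aligned numeric series.
#' @return numeric series, `NA` where `dc <= 0`.
#' @export
pulsation_ratio <- function(ac, dc) {
  if (length(ac) != length(dc)) stop("ac and dc length mismatch")
  pr <- ac / dc
  pr[!is.finite(dc) | dc <= 0] <- NA_real_
  pr
}

#' Modulation ratio (ratio of ratios) of one detector
#'
#' `Phi(t) = pr740(t) / pr850(t)`: the pulsation ratio at the shorter
#' wavelength divided by the pulsation ratio at the longer wavelength.
#' Invalid or zero denominators yield invalid (`NA`) samples.
#'
#' @param pr740,pr850 aligned pulsation-ratio series.
#' @return numeric Phi series with `NA` at invalid samples.
#' @export
modulation_ratio <- function(pr740, pr850) {
  if (length(pr740) != length(pr850)) stop("pulsation ratio series length mismatch")
  phi <- pr740 / pr850
  phi[!is.finite(pr850) | pr850 == 0 | !is.finite(pr740)] <- NA_real_
  phi
}

# centered moving sum/count over a time window [t0 - half, t0 + half]
# (closed on both ends); NA inputs are excluded via cumulative sums, O(n)
window_stats <- function(t, x, t_out, half_window) {
  ord <- order(t)
  t <- t[ord]; x <- x[ord]
  ok <- is.finite(x)
  cs <- cumsum(ifelse(ok, x, 0))
  cn <- cumsum(as.numeric(ok))
  lo <- findInterval(t_out - half_window - 1e-9, t)   # index of last t < lower
  hi <- findInterval(t_out + half_window + 1e-9, t)   # index of last t <= upper
  s <- ifelse(hi > 0, cs[pmax(hi, 1)], 0) - ifelse(lo > 0, cs[pmax(lo, 1)], 0)
  m <- ifelse(hi > 0, cn[pmax(hi, 1)], 0) - ifelse(lo > 0, cn[pmax(lo, 1)], 0)
  list(sum = s, count = m)
}

# centered moving mean emitted on an output grid; NA when count < min_count
window_mean_1hz <- function(t, x, t_out, half_window = 45, min_count = 10) {
  ws <- window_stats(t, x, t_out, half_window)
  out <- ws$sum / ws$count
  out[ws$count < min_count] <- NA_real_
  out
}

#' Outlier rejection and smoothing of a modulation-ratio series
#'
#' Samples whose Phi lies outside `range` are rejected as outliers (they
#' indicate pulsation ratios more than two orders of magnitude apart, i.e. a
#' corrupted measurement). The remaining samples are averaged in a centered
#' 1.5-min window and emitted at 1 sample/s; an output sample is invalid
#' (`NA`) when its window holds fewer than `min_count` non-outlier points.
#'
#' @param t sample times, s (monotone).
#' @param phi modulation-ratio series.
#' @param t_out output times, s; default the integer seconds spanned by `t`.
#' @param range admissible Phi range.
#' @param window smoothing window length, s (centered).
#' @param min_count minimum non-outlier points per window.
#' @return data.frame with columns `t`, `phi` (NA = invalid), `n_window`.
#' @export
reject_and_smooth <- function(t, phi, t_out = NULL, range = c(0.01, 100),
                              window = 90, min_count = 10) {
  if (length(t) != length(phi)) stop("t and phi length mismatch")
  if (is.unsorted(t)) stop("timestamps must be monotone")
  if (is.null(t_out)) t_out <- seq(ceiling(min(t)), floor(max(t)), by = 1)
  keep <- is.finite(phi) & phi >= range[1] & phi <= range[2]
  phi_clean <- ifelse(keep, phi, NA_real_)
  sm <- window_mean_1hz(t, phi_clean, t_out, window / 2, min_count)
  cnt <- window_stats(t, phi_clean, t_out, window / 2)$count
  data.frame(t = t_out, phi = sm, n_window = cnt)
}

#' Hypoxemia labels from sparse blood-gas draws
#'
#' Linearly interpolates the ABG saturation readings onto the requested grid
#' and labels a time point hypoxemic iff the interpolated saturation is
#' strictly below the threshold. Points outside the span of the draws are
#' unlabelable (`NA`).
#'
#' @param abg data.frame with columns `t` (s, strictly increasing) and
#'   `fsao2` (%).
#' @param t_grid times to label, s.
#' @param threshold hypoxemia threshold, %.
#' @return logical vector: `TRUE` = hypoxemic, `NA` outside the draw span.
#' @export
label_samples <- function(abg, t_grid, threshold = 30) {
  if (!all(c("t", "fsao2") %in% names(abg))) stop("abg needs columns t and fsao2")
  if (nrow(abg) < 2) stop("need at least two ABG draws to interpolate")
  if (is.unsorted(abg$t, strictly = TRUE)) stop("ABG times must be strictly increasing")
  if (any(abg$fsao2 < 0 | abg$fsao2 > 100)) stop("fSaO2 must lie in [0, 100] %")
  v <- stats::approx(abg$t, abg$fsao2, xout = t_grid, rule = 1)$y
  v < threshold
}

#' Assemble 1 Hz feature samples for one round
#'
#' Combines the ten smoothed pulsation ratios, the five smoothed modulation
#' ratios, and the hypoxemia labels into the per-second feature table
#' consumed by the classifier. A row is valid iff all 15 features and its
#' label are valid. Each row records the raw-data window
#' `[t - window/2, t + window/2]` used by the smoother, which the
#' cross-validation harness needs for overlap exclusion.
#'
#' @param pulsation matrix (n x 10) of smoothed pulsation ratios, columns
#'   `pr_d{1..5}_{740,850}`.
#' @param modulation matrix (n x 5) of smoothed modulation ratios, columns
#'   `phi_d{1..5}`.
#' @param labels logical vector of length n.
#' @param t 1 Hz timestamps, s.
#' @param round_id round identifier.
#' @param window smoothing window length, s.
#' @return data.frame of class `tfo_features`.
#' @export
assemble_samples <- function(pulsation, modulation, labels, t,
                             round_id = 1L, window = 90) {
  n <- length(t)
  stopifnot(nrow(pulsation) == n, nrow(modulation) == n, length(labels) == n)
  valid <- stats::complete.cases(pulsation) & stats::complete.cases(modulation) &
    !is.na(labels)
  out <- data.frame(t = t, round_id = round_id, pulsation, modulation,
                    label = labels, valid = valid,
                    win_start = t - window / 2, win_end = t + window / 2)
  class(out) <- c("tfo_features", class(out))
  out
}

#' @export
print.tfo_features <- function(x, ...) {
  cat(sprintf("TFO feature samples: %d rows (%d valid) from %d round(s), %d hypoxemic\n",
              nrow(x), sum(x$valid), length(unique(x$round_id)),
              sum(x$label & x$valid, na.rm = TRUE)))
  invisible(x)
}

#' Feature extraction for one processed round
#'
#' Runs the post-processing stage end to end for one round: pulsation ratios
#' per channel, modulation ratios per detector, outlier rejection and 1.5-min
#' smoothing to 1 Hz, labeling from ABG draws, and sample assembly. Pulsation
#' features are the same windowed means that feed the modulation ratio, so
#' the 15 features of a sample are mutually consistent.
#'
#' @param acdc an `acdc_series` from [extract_acdc()].
#' @param abg ABG draw data.frame (`t`, `fsao2`).
#' @param round_id round identifier.
#' @param threshold hypoxemia threshold, %.
#' @param phi_range admissible modulation-ratio range.
#' @param window smoothing window, s.
#' @param min_count minimum points per smoothing window.
#' @return `tfo_features` data.frame (one row per second).
#' @export
compute_features <- function(acdc, abg, round_id = 1L, threshold = 30,
                             phi_range = c(0.01, 100), window = 90,
                             min_count = 10) {
  stopifnot(inherits(acdc, "acdc_series"))
  nd <- length(acdc$ac)
  wl <- acdc$wavelengths
  t <- acdc$t
  t_out <- seq(ceiling(min(t)), floor(max(t)), by = 1)
  pr_cols <- list()
  phi_cols <- list()
  for (d in seq_len(nd)) {
    pr <- lapply(wl, function(w) pulsation_ratio(acdc$ac[[d]][[w]], acdc$dc[[d]][[w]]))
    names(pr) <- wl
    for (w in wl)
      pr_cols[[sprintf("pr_d%d_%s", d, w)]] <-
        window_mean_1hz(t, pr[[w]], t_out, window / 2, min_count)
    phi <- modulation_ratio(pr[[1]], pr[[2]])
    phi_cols[[sprintf("phi_d%d", d)]] <-
      reject_and_smooth(t, phi, t_out, phi_range, window, min_count)$phi
  }
  pulsation <- as.matrix(as.data.frame(pr_cols))
  modulation <- as.matrix(as.data.frame(phi_cols))
  labels <- label_samples(abg, t_out, threshold)
  assemble_samples(pulsation, modulation, labels, t_out, round_id, window)
}
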