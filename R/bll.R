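#' Extinction coefficient table for oxy- and deoxyhemoglobin
#'
#' Holds molar extinction coefficients of oxyhemoglobin (O2Hb) and
#' deoxyhemoglobin (RHb) at the two measurement wavelengths. The defaults are
#' the standard compiled hemoglobin absorption spectra (Prahl compilation) at
#' 740 nm and 850 nm, the wavelength pair used for transabdominal fetal
#' oximetry: fetal saturations sit in the 30-70% range, where this pair
#' separates the two chromophores better than the conventional 660/940 nm
#' choice.
#'
#' @param wavelengths two distinct wavelengths in nm.
#' @param eps_o2hb molar extinction coefficients of O2Hb at `wavelengths`,
#'   in molar^-1 cm^-1.
#' @param eps_rhb molar extinction coefficients of RHb, same units.
#' @return an object of class `extinction_table`.
#' @examples
#' eps <- extinction_table()
#' saturation_from_phi(phi_from_state(chromophore_state(0.4), eps), eps)
#' @export
extinction_table <- function(wavelengths = c(740, 850),
                             eps_o2hb = c(446.0, 1058.0),
                             eps_rhb = c(1115.88, 691.32)) {
  if (length(wavelengths) != 2L || length(eps_o2hb) != 2L || length(eps_rhb) != 2L)
    stop("extinction_table requires exactly two wavelengths")
  if (wavelengths[1] == wavelengths[2])
    stop("the two wavelengths must be distinct")
  if (any(!is.finite(c(eps_o2hb, eps_rhb))) || any(c(eps_o2hb, eps_rhb) <= 0))
    stop("all extinction coefficients must be strictly positive")
  m <- rbind(c(eps_o2hb[1], eps_rhb[1]), c(eps_o2hb[2], eps_rhb[2]))
  if (abs(det(m)) < 1e-10 * max(abs(m))^2)
    stop("extinction matrix is singular: the two wavelengths carry no independent information")
  structure(
    list(wavelengths = as.numeric(wavelengths),
         eps_o2hb = stats::setNames(as.numeric(eps_o2hb), wavelengths),
         eps_rhb = stats::setNames(as.numeric(eps_rhb), wavelengths)),
    class = "extinction_table")
}

#' @export
print.extinction_table <- function(x, ...) {
  cat("Extinction table (molar^-1 cm^-1)\n")
  print(data.frame(wavelength_nm = x$wavelengths,
                   eps_o2hb = unname(x$eps_o2hb),
                   eps_rhb = unname(x$eps_rhb)))
  invisible(x)
}

#' Chromophore state of the pulsating arterial compartment
#'
#' Describes the pulsatile change in the optical path: oxygen saturation S
#' (fraction of total hemoglobin bound to oxygen), the change in total
#' hemoglobin concentration over a cardiac cycle, and the mean photon path
#' length (assumed equal at both wavelengths).
#'
#' @param saturation oxygen saturation S, fraction in \[0, 1\]; may be a vector
#'   (e.g. a saturation trajectory).
#' @param delta_c_thb change in total hemoglobin concentration, mM (>= 0).
#' @param mean_path mean photon path length, cm (> 0).
#' @return object of class `chromophore_state`.
#' @export
chromophore_state <- function(saturation, delta_c_thb = 2e-3, mean_path = 10) {
  if (any(!is.finite(saturation)) || any(saturation < 0) || any(saturation > 1))
    stop("saturation must lie in [0, 1]")
  if (!is.finite(delta_c_thb) || delta_c_thb < 0)
    stop("delta_c_thb must be non-negative (mM)")
  if (!is.finite(mean_path) || mean_path <= 0)
    stop("mean_path must be strictly positive (cm)")
  structure(list(saturation = as.numeric(saturation),
                 delta_c_thb = delta_c_thb,
                 mean_path = mean_path),
            class = "chromophore_state")
}

#' @export
print.chromophore_state <- function(x, ...) {
  cat(sprintf("Chromophore state: S = %s, dC_THb = %g mM, <L> = %g cm\n",
              if (length(x$saturation) > 3)
                sprintf("[%g..%g] (n=%d)", min(x$saturation), max(x$saturation),
                        length(x$saturation))
              else paste(signif(x$saturation, 4), collapse = ", "),
              x$delta_c_thb, x$mean_path))
  invisible(x)
}

eps_at <- function(eps, wavelength) {
  i <- match(wavelength, eps$wavelengths)
  if (is.na(i))
    stop(sprintf("unknown wavelength %s nm (table holds %s)", wavelength,
                 paste(eps$wavelengths, collapse = ", ")))
  c(o2hb = unname(eps$eps_o2hb[i]), rhb = unname(eps$eps_rhb[i]))
}

#' Pulsatile change in optical absorbance (modified Beer-Lambert law)
#'
#' Computes the change in absorbance at one wavelength caused by a pulsatile
#' change in arterial blood volume:
#' dA = (dC_O2Hb * eps_O2Hb + dC_RHb * eps_RHb) * <L>, with
#' dC_O2Hb = S * dC_THb and dC_RHb = (1 - S) * dC_THb. Concentrations are
#' given in mM and converted to molar internally, so dA is dimensionless.
#'
#' @param state a [chromophore_state()].
#' @param eps an [extinction_table()].
#' @param wavelength one of the table's wavelengths, nm.
#' @return numeric vector of absorbance changes (one per saturation value).
#' @export
delta_absorbance <- function(state, eps = extinction_table(), wavelength) {
  stopifnot(inherits(state, "chromophore_state"), inherits(eps, "extinction_table"))
  e <- eps_at(eps, wavelength)
  s <- state$saturation
  dc_molar <- state$delta_c_thb * 1e-3   # mM -> M
  (s * dc_molar * e[["o2hb"]] + (1 - s) * dc_molar * e[["rhb"]]) * state$mean_path
}

#' Modulation ratio Phi implied by a chromophore state
#'
#' The ratio of absorbance changes at the two wavelengths,
#' Phi = dA(lambda1) / dA(lambda2). Because the mean photon path is assumed
#' equal at both wavelengths, dC_THb and <L> cancel and Phi depends only on
#' saturation and the extinction coefficients.
#'
#' @inheritParams delta_absorbance
#' @return numeric vector of Phi values.
#' @export
phi_from_state <- function(state, eps = extinction_table()) {
  da1 <- delta_absorbance(state, eps, eps$wavelengths[1])
  da2 <- delta_absorbance(state, eps, eps$wavelengths[2])
  if (any(da2 == 0))
    stop("degenerate denominator: absorbance change at the second wavelength is zero")
  da1 / da2
}

#' Oxygen saturation from the modulation ratio
#'
#' Closed-form inverse of [phi_from_state()]:
#' S = (Phi * eps_RHb2 - eps_RHb1) /
#'     (eps_O2Hb1 - eps_RHb1 - Phi * (eps_O2Hb2 - eps_RHb2)).
#' The raw algebraic value is returned without clamping; values outside
#' \[0, 1\] indicate a model violation and are flagged via the
#' `outside_unit_interval` attribute.
#'
#' @param phi numeric vector of modulation ratios.
#' @param eps an [extinction_table()].
#' @param tol relative tolerance below which the denominator is treated as
#'   zero (pole of the inverse).
#' @return numeric vector of saturations with attribute
#'   `outside_unit_interval` (logical vector).
#' @export
saturation_from_phi <- function(phi, eps = extinction_table(), tol = 1e-12) {
  stopifnot(is.numeric(phi), inherits(eps, "extinction_table"))
  e1 <- eps_at(eps, eps$wavelengths[1])
  e2 <- eps_at(eps, eps$wavelengths[2])
  den <- e1[["o2hb"]] - e1[["rhb"]] - phi * (e2[["o2hb"]] - e2[["rhb"]])
  scale <- max(abs(c(e1, e2)))
  if (any(!is.finite(den)) || any(abs(den) < tol * scale))
    stop("denominator of the saturation inverse is (near) zero: Phi at the pole")
  s <- (phi * e2[["rhb"]] - e1[["rhb"]]) / den
  attr(s, "outside_unit_interval") <- s < 0 | s > 1
  s
}

#' Read / write an extinction table as CSV
#'
#' Two-row CSV with columns `wavelength_nm`, `eps_o2hb`, `eps_rhb`.
#'
#' @param path file path.
#' @return [read_extinction_csv()] returns an [extinction_table()];
#'   [write_extinction_csv()] returns `path` invisibly.
#' @export
read_extinction_csv <- function(path) {
  d <- utils::read.csv(path)
  req <- c("wavelength_nm", "eps_o2hb", "eps_rhb")
  if (!all(req %in% names(d)))
    stop("extinction CSV must have columns wavelength_nm, eps_o2hb, eps_rhb")
  extinction_table(d$wavelength_nm, d$eps_o2hb, d$eps_rhb)
}

#' @rdname read_extinction_csv
#' @param eps an [extinction_table()].
#' @export
write_extinction_csv <- function(eps, path) {
  stopifnot(inherits(eps, "extinction_table"))
  utils::write.csv(data.frame(wavelength_nm = eps$wavelengths,
                              eps_o2hb = unname(eps$eps_o2hb),
                              eps_rhb = unname(eps$eps_rhb)),
                   path, row.names = FALSE)
  invisible(path)
}
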