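#' Read / write pipeline tables as CSV
#'
#' Plain-text serialization of the pipeline's tabular artifacts: ground-truth
#' traces (`t`, `fsao2`, `fhr`, `mhr`), ABG draws (`t`, `fsao2`), FHR
#' reference traces (`t`, `fhr_hz`) and 1 Hz feature tables.
#'
#' @param truth a `tfo_truth`.
#' @param path file path.
#' @return the written path (invisibly) or the restored object.
#' @export
write_truth_csv <- function(truth, path) {
  stopifnot(inherits(truth, "tfo_truth"))
  utils::write.csv(data.frame(t = truth$t, fsao2 = truth$fsao2,
                              fhr = truth$fhr, mhr = truth$mhr),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @param abg ABG data.frame (`t`, `fsao2`).
#' @export
write_abg_csv <- function(abg, path) {
  utils::write.csv(abg[, c("t", "fsao2")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_abg_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("t", "fsao2") %in% names(d))) stop("ABG CSV needs columns t, fsao2")
  d
}

#' @rdname write_truth_csv
#' @param trace FHR trace data.frame (`t`, `fhr_hz`).
#' @export
write_fhr_csv <- function(trace, path) {
  utils::write.csv(trace[, c("t", "fhr_hz")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_fhr_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("t", "fhr_hz") %in% names(d))) stop("FHR CSV needs columns t, fhr_hz")
  d
}

#' @rdname write_truth_csv
#' @param features a `tfo_features` table.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_features_csv <- function(path) {
  d <- utils::read.csv(path)
  req <- c("t", "round_id", "label", "valid", "win_start", "win_end")
  if (!all(req %in% names(d)))
    stop("feature CSV is missing required columns")
  d$label <- as.logical(d$label)
  d$valid <- as.logical(d$valid)
  class(d) <- c("tfo_features", class(d))
  d
}
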