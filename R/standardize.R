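#' Feature standardization (across rounds or per round)
#'
#' Two schemes mirror the two feature families. Pulsation ratios encode the
#' measurement context (attenuation, geometry) of a round and are
#' standardized *across rounds*: one mean/sd per feature over the whole fit
#' set. Modulation ratios carry the saturation signal with strong
#' subject-specific sensitivity and are standardized *per round*: one
#' mean/sd per (round, feature). Standard deviations are population
#' (divide by n) moments.
#'
#' @param x numeric matrix (samples x features), column names required.
#' @param mode `"across_rounds"` or `"per_round"`.
#' @param rounds round identifier per row; required for `"per_round"`.
#' @return object of class `standardizer`.
#' @export
fit_standardizer <- function(x, mode = c("across_rounds", "per_round"),
                             rounds = NULL) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("feature matrix must have column names")
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  if (mode == "across_rounds") {
    if (nrow(x) < 2) stop("need at least two samples to fit a standardizer")
    means <- colMeans(x)
    sds <- apply(x, 2, pop_sd)
    bad <- sds <= 0
    if (any(bad))
      stop(sprintf("zero variance in feature(s): %s",
                   paste(colnames(x)[bad], collapse = ", ")))
    st <- list(mode = mode, means = means, sds = sds)
  } else {
    if (is.null(rounds) || length(rounds) != nrow(x))
      stop("per_round standardization needs a round id per row")
    groups <- split(seq_len(nrow(x)), rounds)
    stats_by_round <- lapply(groups, function(idx) {
      if (length(idx) < 2)
        stop("need at least two samples per round to fit a standardizer")
      m <- colMeans(x[idx, , drop = FALSE])
      s <- apply(x[idx, , drop = FALSE], 2, pop_sd)
      bad <- s <= 0
      if (any(bad))
        stop(sprintf("zero variance in feature(s) %s of round %s",
                     paste(colnames(x)[bad], collapse = ", "),
                     rounds[idx[1]]))
      list(means = m, sds = s)
    })
    st <- list(mode = mode, by_round = stats_by_round)
  }
  structure(st, class = "standardizer")
}

#' Apply / invert a fitted standardizer
#'
#' @param st a `standardizer`.
#' @param x matrix with the fitted columns.
#' @param rounds round ids (per_round mode only). Rounds unseen at fit time
#'   are an error.
#' @return transformed matrix.
#' @export
apply_standardizer <- function(st, x, rounds = NULL) {
  stopifnot(inherits(st, "standardizer"))
  x <- as.matrix(x)
  if (st$mode == "across_rounds")
    return(sweep(sweep(x, 2, st$means), 2, st$sds, "/"))
  if (is.null(rounds)) stop("per_round standardizer needs round ids")
  out <- x
  for (r in unique(rounds)) {
    s <- st$by_round[[as.character(r)]]
    if (is.null(s)) stop(sprintf("round %s was not seen when fitting", r))
    idx <- rounds == r
    out[idx, ] <- sweep(sweep(x[idx, , drop = FALSE], 2, s$means), 2, s$sds, "/")
  }
  out
}

#' @rdname apply_standardizer
#' @export
invert_standardizer <- function(st, x, rounds = NULL) {
  stopifnot(inherits(st, "standardizer"))
  x <- as.matrix(x)
  if (st$mode == "across_rounds")
    return(sweep(sweep(x, 2, st$sds, "*"), 2, st$means, "+"))
  if (is.null(rounds)) stop("per_round standardizer needs round ids")
  out <- x
  for (r in unique(rounds)) {
    s <- st$by_round[[as.character(r)]]
    if (is.null(s)) stop(sprintf("round %s was not seen when fitting", r))
    idx <- rounds == r
    out[idx, ] <- sweep(sweep(x[idx, , drop = FALSE], 2, s$sds, "*"), 2, s$means, "+")
  }
  out
}
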