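#' Staggered round-based five-fold assignment
#'
#' Each round's (time-sorted, valid) samples are split into five contiguous
#' folds. The validation fold is staggered across rounds: round k (in round
#' order) starts its iteration-0 validation block at
#' `p = 20% * ((k - 1) mod 5)` of the round, and iteration j shifts every
#' round's start by `20% * j` modulo 100%. Fold boundaries are
#' `floor(n*l) < i <= floor((n + 0.2) * l)` with 1-based indices, so over the
#' five iterations every index is validated exactly once and remainder
#' samples (l not divisible by 5) land in the last fold of the cycle.
#'
#' @param samples a `tfo_features` data.frame (or any data.frame with
#'   `round_id`, `t`, `valid`, `win_start`, `win_end`).
#' @param valid_only drop invalid samples before assignment (fold lengths
#'   then count valid samples only).
#' @return list of 5 `fold_assignment` objects (iterations j = 0..4), each a
#'   list with `iteration`, `val` and `train` (integer row indices into the
#'   retained sample table), `rounds` (per-round bookkeeping) and the
#'   retained `samples`.
#' @export
assign_folds <- function(samples, valid_only = TRUE) {
  stopifnot(all(c("round_id", "t") %in% names(samples)))
  if (valid_only && "valid" %in% names(samples))
    samples <- samples[samples$valid, , drop = FALSE]
  rounds <- unique(samples$round_id)
  ord <- order(match(samples$round_id, rounds), samples$t)
  samples <- samples[ord, , drop = FALSE]
  rownames(samples) <- NULL
  lapply(0:4, function(j) {
    val <- integer(0); train <- integer(0); per_round <- list()
    for (k in seq_along(rounds)) {
      idx <- which(samples$round_id == rounds[k])
      l <- length(idx)
      if (l < 5) stop(sprintf("round %s has %d samples; need at least 5", rounds[k], l))
      vset <- fold_indices(l, k, j)
      val <- c(val, idx[vset])
      train <- c(train, idx[setdiff(seq_len(l), vset)])
      per_round[[as.character(rounds[k])]] <-
        list(l = l, start_tenths = fold_start_tenths(k, j), val_local = vset)
    }
    structure(list(iteration = j, val = val, train = train,
                   discarded = integer(0), rounds = per_round,
                   samples = samples),
              class = "fold_assignment")
  })
}

# start fraction in tenths (exact integer arithmetic): round position k
# (1-based), iteration j
fold_start_tenths <- function(k, j) {
  (2L * ((k - 1L) %% 5L) + 2L * j) %% 10L
}

#' Validation indices of one round, one iteration
#'
#' Hand-traceable core of the fold scheme: the validation set of a round of
#' length `l` at round position `k` (1-based) in iteration `j` (0-based) is
#' `{i : floor(n*l) < i <= floor((n + 0.2) * l)}` where
#' `n = (0.2*(k-1) + 0.2*j) mod 1`. Computed in integer tenths so floating
#' point cannot shift a boundary.
#'
#' @param l round length (>= 5).
#' @param k round position (1-based).
#' @param j iteration (0..4).
#' @return integer vector of 1-based validation indices.
#' @export
fold_indices <- function(l, k, j) {
  n10 <- fold_start_tenths(k, j)
  lo <- (n10 * l) %/% 10L
  hi <- ((n10 + 2L) * l) %/% 10L
  seq.int(lo + 1L, hi)
}

#' Discard training samples whose smoothing windows touch validation windows
#'
#' Every 1 Hz sample is an average over a raw-data window
#' `[win_start, win_end]`. A training sample whose window strictly overlaps
#' the window of any validation sample of the same round leaks validation
#' raw data into training and is discarded. Windows that merely touch at an
#' endpoint do not overlap.
#'
#' @param assignment a `fold_assignment` from [assign_folds()].
#' @return the assignment with the overlapping indices moved from `train` to
#'   `discarded`.
#' @export
exclude_overlap <- function(assignment) {
  stopifnot(inherits(assignment, "fold_assignment"))
  s <- assignment$samples
  if (!all(c("win_start", "win_end") %in% names(s)))
    stop("samples must carry win_start / win_end")
  drop <- logical(length(assignment$train))
  for (r in unique(s$round_id)) {
    vr <- assignment$val[s$round_id[assignment$val] == r]
    tr_sel <- which(s$round_id[assignment$train] == r)
    if (length(vr) == 0 || length(tr_sel) == 0) next
    v_lo <- min(s$win_start[vr]); v_hi <- max(s$win_end[vr])
    tr <- assignment$train[tr_sel]
    drop[tr_sel] <- drop[tr_sel] |
      (s$win_start[tr] < v_hi & s$win_end[tr] > v_lo)
  }
  assignment$discarded <- assignment$train[drop]
  assignment$train <- assignment$train[!drop]
  assignment
}

#' Round-based cross-validation of the fusion classifier
#'
#' Runs the full validation protocol: per-round standardization of the
#' modulation ratios (each round uses its own moments), then for each of the
#' five staggered iterations: fold assignment, overlap exclusion,
#' across-round standardization of the pulsation ratios fitted on the
#' training samples, network training, and evaluation on the pooled
#' validation samples of all rounds. The summary is the mean of the five
#' iterations' metrics.
#'
#' @param samples a `tfo_features` table covering all rounds.
#' @param spec a [network_spec()].
#' @param config a [train_config()]; iteration j trains with seed
#'   `config$seed + j`.
#' @param pulsation_fit `"train"` fits the pulsation standardizer on training
#'   samples only (no leakage); `"all"` uses all samples.
#' @param n_boot bootstrap resamples per iteration's AUC CI.
#' @return object of class `cv_result`: `iterations` (list of per-iteration
#'   lists with `metrics`, `counts`, `history`, `best_epoch`), `counts`
#'   (Table-shaped data.frame of per-iteration class counts), `summary`
#'   (mean metrics).
#' @export
run_cross_validation <- function(samples, spec = network_spec(),
                                 config = train_config(),
                                 pulsation_fit = c("train", "all"),
                                 n_boot = 200) {
  pulsation_fit <- match.arg(pulsation_fit)
  pr_cols <- grep("^pr_d", names(samples), value = TRUE)
  phi_cols <- grep("^phi_d", names(samples), value = TRUE)
  if (length(pr_cols) != spec$n_pulsation || length(phi_cols) != spec$n_modulation)
    stop("sample table does not match the network specification")
  assignments <- assign_folds(samples)
  s <- assignments[[1]]$samples
  if (!any(s$label) || all(s$label))
    stop("cohort must contain both classes")
  # per-round modulation standardization on each round's own samples
  st_mod <- fit_standardizer(s[, phi_cols], "per_round", s$round_id)
  mod_all <- apply_standardizer(st_mod, s[, phi_cols], s$round_id)
  iterations <- vector("list", 5)
  counts <- data.frame()
  for (j in 0:4) {
    a <- exclude_overlap(assignments[[j + 1]])
    tr <- a$train; va <- a$val
    y_tr <- as.numeric(s$label[tr]); y_va <- as.numeric(s$label[va])
    if (length(unique(y_tr)) < 2)
      stop(sprintf("iteration %d: training set contains a single class", j))
    fit_rows <- if (pulsation_fit == "train") tr else seq_len(nrow(s))
    st_pr <- fit_standardizer(s[fit_rows, pr_cols], "across_rounds")
    pr_tr <- apply_standardizer(st_pr, s[tr, pr_cols])
    pr_va <- apply_standardizer(st_pr, s[va, pr_cols])
    model <- build_network(spec, seed = config$seed + j)
    fit <- train_network(model, pr_tr, mod_all[tr, , drop = FALSE], y_tr,
                         pr_va, mod_all[va, , drop = FALSE], y_va, config)
    pred <- predict_network(fit$model, pr_va, mod_all[va, , drop = FALSE],
                            config$threshold)
    metrics <- suppressWarnings(
      evaluate_predictions(pred$prob, y_va, config$threshold,
                           n_boot = n_boot, boot_seed = config$seed + j))
    counts <- rbind(counts, data.frame(
      iteration = j + 1,
      hypoxemic_val = sum(y_va == 1), hypoxemic_train = sum(y_tr == 1),
      normoxemic_val = sum(y_va == 0), normoxemic_train = sum(y_tr == 0),
      discarded = length(a$discarded),
      accuracy = metrics$accuracy, sensitivity = metrics$sensitivity,
      specificity = metrics$specificity, precision = metrics$precision,
      f1 = metrics$f1, auc = metrics$auc))
    iterations[[j + 1]] <- list(metrics = metrics, assignment = a,
                                history = fit$history,
                                best_epoch = fit$best_epoch,
                                prob = pred$prob, labels = y_va)
  }
  metric_cols <- c("accuracy", "sensitivity", "specificity", "precision",
                   "f1", "auc")
  summary <- colMeans(counts[, metric_cols], na.rm = TRUE)
  structure(list(iterations = iterations, counts = counts, summary = summary),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Round-based five-fold cross-validation\n")
  print(x$counts[, c("iteration", "hypoxemic_val", "hypoxemic_train",
                     "normoxemic_val", "normoxemic_train", "accuracy",
                     "sensitivity", "specificity", "precision", "f1", "auc")],
        row.names = FALSE, digits = 3)
  cat("Mean over iterations:\n")
  print(round(x$summary, 3))
  invisible(x)
}
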