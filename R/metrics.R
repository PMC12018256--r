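#' Classification metrics, ROC and AUC for one validation set
#'
#' Builds the confusion matrix at the decision threshold (hypoxemia =
#' positive), the derived rates, the ROC curve obtained by sweeping the
#' threshold over the unique predicted probabilities, the trapezoid-rule
#' AUC, and a stratified-bootstrap percentile confidence interval for the
#' AUC. With a single-class validation set the undefined rate (sensitivity
#' or specificity) is reported as `NaN` with a warning, as happens for
#' all-hypoxemic rounds.
#'
#' @param prob predicted probabilities.
#' @param labels true labels (logical or 0/1; `TRUE` = hypoxemic).
#' @param threshold decision threshold (positive iff `prob >= threshold`).
#' @param n_boot bootstrap resamples for the AUC CI (0 = skip).
#' @param boot_seed RNG seed for the bootstrap.
#' @param ci_level confidence level.
#' @return object of class `metrics_report`.
#' @export
evaluate_predictions <- function(prob, labels, threshold = 0.5,
                                 n_boot = 1000, boot_seed = 1,
                                 ci_level = 0.95) {
  y <- as.logical(labels)
  if (length(prob) != length(y) || length(y) == 0)
    stop("prob and labels must be non-empty and aligned")
  pred <- prob >= threshold
  tp <- sum(pred & y); fp <- sum(pred & !y)
  tn <- sum(!pred & !y); fn <- sum(!pred & y)
  n <- length(y)
  acc <- (tp + tn) / n
  sens <- if (tp + fn > 0) tp / (tp + fn) else NaN
  spec <- if (tn + fp > 0) tn / (tn + fp) else NaN
  prec <- if (tp + fp > 0) tp / (tp + fp) else NaN
  f1 <- if (is.finite(prec) && is.finite(sens) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NaN
  if (!any(y) || all(y))
    warning("single-class validation set: sensitivity/specificity/AUC partially undefined")
  roc <- roc_points(prob, y)
  auc <- if (any(y) && !all(y)) trapezoid_auc(roc$fpr, roc$tpr) else NA_real_
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0 && is.finite(auc)) {
    pos <- which(y); neg <- which(!y)
    aucs <- with_seed(boot_seed, {
      vapply(seq_len(n_boot), function(b) {
        i <- c(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
        r <- roc_points(prob[i], y[i])
        trapezoid_auc(r$fpr, r$tpr)
      }, numeric(1))
    })
    a <- (1 - ci_level) / 2
    ci <- unname(stats::quantile(aucs, c(a, 1 - a)))
  }
  structure(list(confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 n = n, accuracy = acc, sensitivity = sens,
                 specificity = spec, precision = prec, f1 = f1,
                 roc = roc, auc = auc, auc_ci = ci, threshold = threshold),
            class = "metrics_report")
}

# ROC by sweeping the threshold over the unique probabilities
roc_points <- function(prob, y) {
  thr <- sort(unique(prob), decreasing = TRUE)
  npos <- sum(y); nneg <- sum(!y)
  tpr <- vapply(thr, function(th) if (npos > 0) sum(prob >= th & y) / npos else NaN,
                numeric(1))
  fpr <- vapply(thr, function(th) if (nneg > 0) sum(prob >= th & !y) / nneg else NaN,
                numeric(1))
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  x <- c(fpr[o], 1); yv <- c(tpr[o], 1)
  sum(diff(x) * (utils::head(yv, -1) + utils::tail(yv, -1)) / 2)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "Metrics (n=%d): acc %.3f | sens %.3f | spec %.3f | prec %.3f | F1 %.3f | AUC %s\n",
    x$n, x$accuracy, x$sensitivity, x$specificity, x$precision, x$f1,
    if (is.finite(x$auc)) sprintf("%.3f (CI %.3f-%.3f)", x$auc,
                                  x$auc_ci[1], x$auc_ci[2]) else "NA"))
  cm <- x$confusion
  cat(sprintf("  confusion: TP %d  FP %d  TN %d  FN %d\n",
              cm["TP"], cm["FP"], cm["TN"], cm["FN"]))
  invisible(x)
}
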