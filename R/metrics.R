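#' Classification metrics report
#'
#' Confusion counts and the derived rates: accuracy `(TP+TN)/N`,
#' specificity `TN/(TN+FP)`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`
#' and `F1 = 2*precision*recall/(precision+recall)`. A rate whose
#' denominator is zero is reported as 0 and its name recorded in `flagged`
#' (kept numeric so the JSON report stays portable). When probabilities are
#' supplied, the ROC curve is traced by sweeping a threshold over the
#' unique probability values (plus an all-negative starting point) and the
#' AUC is computed by the trapezoid rule over (FPR, TPR).
#'
#' @param truth Integer 0/1 true labels.
#' @param predicted Integer 0/1 predicted labels, same length.
#' @param prob Optional numeric scores/probabilities for the ROC sweep.
#' @return Object of class `metrics_report`: confusion counts, the five
#'   rates, `flagged`, `n`, and (with `prob`) `roc` (threshold, fpr, tpr)
#'   and `auc`.
#' @examples
#' m <- compute_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' m$accuracy
#' @export
compute_metrics <- function(truth, predicted, prob = NULL) {
  if (length(truth) != length(predicted))
    stop("label vectors have different lengths", call. = FALSE)
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  tp <- sum(truth == 1L & predicted == 1L)
  tn <- sum(truth == 0L & predicted == 0L)
  fp <- sum(truth == 0L & predicted == 1L)
  fn <- sum(truth == 1L & predicted == 0L)
  n <- length(truth)
  flagged <- character(0)
  rate <- function(num, den, name) {
    if (den == 0) { flagged <<- c(flagged, name); 0 } else num / den
  }
  accuracy <- rate(tp + tn, n, "accuracy")
  specificity <- rate(tn, tn + fp, "specificity")
  precision <- rate(tp, tp + fp, "precision")
  recall <- rate(tp, tp + fn, "recall")
  f1 <- rate(2 * precision * recall, precision + recall, "f1")
  roc <- NULL; auc <- NULL
  if (!is.null(prob)) {
    if (length(prob) != n) stop("`prob` length mismatch", call. = FALSE)
    ths <- c(Inf, sort(unique(prob), decreasing = TRUE))
    pos <- sum(truth == 1L); neg <- sum(truth == 0L)
    tpr <- fpr <- numeric(length(ths))
    for (i in seq_along(ths)) {
      pred_i <- prob >= ths[i]
      tpr[i] <- if (pos > 0) sum(pred_i & truth == 1L) / pos else 0
      fpr[i] <- if (neg > 0) sum(pred_i & truth == 0L) / neg else 0
    }
    roc <- data.frame(threshold = ths, fpr = fpr, tpr = tpr)
    auc <- if (pos > 0 && neg > 0) {
      sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
    } else {
      flagged <- c(flagged, "auc"); 0
    }
  }
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, n = n,
                 accuracy = accuracy, specificity = specificity,
                 precision = precision, recall = recall, f1 = f1,
                 flagged = flagged, roc = roc, auc = auc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report (n = %d): TP %d  TN %d  FP %d  FN %d\n",
              x$n, x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("  accuracy %.4f  specificity %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
              x$accuracy, x$specificity, x$precision, x$recall, x$f1))
  if (!is.null(x$auc)) cat(sprintf("  AUC %.4f\n", x$auc))
  if (length(x$flagged))
    cat("  undefined (reported as 0):", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

metrics_to_list <- function(m) {
  list(n = m$n, tp = m$tp, tn = m$tn, fp = m$fp, fn = m$fn,
       accuracy = m$accuracy, specificity = m$specificity,
       precision = m$precision, recall = m$recall, f1 = m$f1,
       auc = m$auc, flagged = as.list(m$flagged))
}

#' Write a metrics report to disk
#'
#' Writes `metrics.json` (full-precision values), `roc.csv` (the threshold
#' sweep) and a human-readable `summary.txt` under `dir`. [read_report()]
#' returns the JSON values; the write/read round trip preserves every
#' number.
#'
#' @param metrics A [compute_metrics()] report.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(metrics, dir) {
  stopifnot(inherits(metrics, "metrics_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(metrics_to_list(metrics),
                       file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(metrics$roc))
    utils::write.csv(metrics$roc, file.path(dir, "roc.csv"),
                     row.names = FALSE)
  con <- file(file.path(dir, "summary.txt"), "w")
  sink(con); print(metrics); sink()
  close(con)
  invisible(dir)
}

#' @rdname write_report
#' @export
read_report <- function(dir) {
  jsonlite::read_json(file.path(dir, "metrics.json"), simplifyVector = TRUE)
}
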