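#' Evaluation metrics for link prediction
#'
#' Thresholded confusion-matrix metrics (accuracy, precision, recall, false
#' positive rate, Matthews correlation coefficient) plus the threshold-free
#' ranking metrics AUROC and AUPR, both computed by trapezoidal integration
#' over the curve traced by sweeping the decision threshold through every
#' distinct score (tied scores move as one group, so AUROC equals the
#' normalized Mann-Whitney U statistic with the usual tie correction).
#'
#' A metric whose denominator is zero (e.g. precision with no predicted
#' positives) is reported as 0 and the metric's name is recorded in the
#' report's `degenerate` field.
#'
#' @param scores numeric scores in `[0, 1]` (higher = more likely linked).
#' @param labels 0/1 truth labels; both classes must be present for
#'   AUROC/AUPR.
#' @param threshold decision threshold for the confusion-matrix metrics
#'   (`score >= threshold` predicts a link), default 0.5.
#' @return An object of class `metrics_report`: list with `acc`,
#'   `precision`, `recall`, `fpr`, `auroc`, `aupr`, `mcc`, `threshold`,
#'   `counts` (TP/FP/TN/FN), `roc_points` (data frame `fpr`, `tpr`),
#'   `pr_points` (data frame `recall`, `precision`) and `degenerate`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2) {
    stop("both classes must be present to compute AUROC/AUPR")
  }
  pred <- scores >= threshold
  TP <- sum(pred & labels == 1L)
  FP <- sum(pred & labels == 0L)
  FN <- sum(!pred & labels == 1L)
  TN <- sum(!pred & labels == 0L)
  degenerate <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      return(0)
    }
    num / den
  }
  precision <- safe(TP, TP + FP, "precision")
  recall <- safe(TP, TP + FN, "recall")
  fpr <- safe(FP, FP + TN, "fpr")
  acc <- (TP + TN) / length(labels)
  mcc_den <- sqrt(as.numeric(TP + FP)) * sqrt(as.numeric(TP + FN)) *
    sqrt(as.numeric(TN + FP)) * sqrt(as.numeric(TN + FN))
  mcc <- if (mcc_den == 0) {
    degenerate <- c(degenerate, "mcc")
    0
  } else {
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / mcc_den
  }
  curves <- ranking_curves(scores, labels)
  structure(list(acc = acc, precision = precision, recall = recall,
                 fpr = fpr, auroc = curves$auroc, aupr = curves$aupr,
                 mcc = mcc, threshold = threshold,
                 counts = c(TP = TP, FP = FP, TN = TN, FN = FN),
                 roc_points = curves$roc, pr_points = curves$pr,
                 degenerate = degenerate),
            class = "metrics_report")
}

# ROC and PR curves over the distinct-score threshold sweep.
ranking_curves <- function(scores, labels) {
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # group tied scores: cumulative counts at the end of each tie group
  last_of_group <- which(!duplicated(s, fromLast = TRUE))
  cum_tp <- cumsum(l)[last_of_group]
  cum_fp <- cumsum(1L - l)[last_of_group]
  tpr <- cum_tp / n_pos
  fpr <- cum_fp / n_neg
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  auroc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                  utils::tail(roc$tpr, -1)) / 2)
  precision <- cum_tp / (cum_tp + cum_fp)
  recall <- tpr
  pr <- data.frame(recall = c(0, recall), precision = c(precision[1], precision))
  aupr <- sum(diff(pr$recall) * (utils::head(pr$precision, -1) +
                                   utils::tail(pr$precision, -1)) / 2)
  list(roc = roc, pr = pr, auroc = auroc, aupr = aupr)
}

#' @exportS3Method base::print
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "Metrics @ threshold %.3g: ACC %.4f | precision %.4f | recall %.4f | AUROC %.4f | AUPR %.4f | MCC %.4f\n",
    x$threshold, x$acc, x$precision, x$recall, x$auroc, x$aupr, x$mcc))
  if (length(x$degenerate)) {
    cat("  zero-denominator metrics reported as 0:",
        paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a metrics report to disk
#'
#' Scalar metrics go to `<stem>.json` (machine-readable) and
#' `<stem>.tsv` (aligned columns); curve points go to `<stem>_roc.tsv` and
#' `<stem>_pr.tsv`, two columns each.
#'
#' @param report a `metrics_report`.
#' @param stem output path stem (no extension).
#' @export
write_metrics <- function(report, stem) {
  scalars <- report[c("acc", "precision", "recall", "fpr", "auroc", "aupr",
                      "mcc", "threshold")]
  jsonlite::write_json(scalars, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(data.frame(metric = names(scalars),
                                value = unlist(scalars)),
                     paste0(stem, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$roc_points, paste0(stem, "_roc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$pr_points, paste0(stem, "_pr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(stem)
}

# Mean of the scalar metrics across a list of reports.
mean_metrics <- function(reports) {
  keys <- c("acc", "precision", "recall", "fpr", "auroc", "aupr", "mcc")
  colMeans(do.call(rbind, lapply(reports, function(r) unlist(r[keys]))))
}
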