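#' Classification metrics: ACC, MCC, AUC, AUPR
#'
#' ACC and MCC come from the thresholded 2x2 confusion matrix (an MCC whose
#' denominator vanishes is defined as 0).  AUC is the rank (Wilcoxon)
#' statistic, equivalent to the trapezoidal area under the ROC curve, with
#' ties counted one half.  AUPR is the step-interpolated area under the
#' precision-recall curve (the average-precision convention).
#'
#' @param y binary labels.
#' @param y_hat predicted probabilities or scores.
#' @param threshold decision threshold for ACC/MCC.
#' @param allow_degenerate if TRUE, a single-class `y` yields NA for
#'   AUC/AUPR instead of an error.
#' @return named list with ACC, MCC, AUC, AUPR.
#' @export
compute_metrics <- function(y, y_hat, threshold = 0.5,
                            allow_degenerate = FALSE) {
  if (length(y) != length(y_hat)) stop("y and y_hat differ in length")
  pred <- classify(y_hat, threshold)
  tp <- sum(pred == 1L & y == 1L); tn <- sum(pred == 0L & y == 0L)
  fp <- sum(pred == 1L & y == 0L); fn <- sum(pred == 0L & y == 1L)
  acc <- (tp + tn) / length(y)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  npos <- sum(y == 1L); nneg <- sum(y == 0L)
  if (npos == 0L || nneg == 0L) {
    if (!allow_degenerate)
      stop("AUC/AUPR undefined: y contains a single class")
    return(list(ACC = acc, MCC = mcc, AUC = NA_real_, AUPR = NA_real_))
  }
  r <- rank(y_hat, ties.method = "average")
  auc <- (sum(r[y == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  list(ACC = acc, MCC = mcc, AUC = auc, AUPR = average_precision(y, y_hat))
}

# step-interpolated area under the precision-recall curve
average_precision <- function(y, y_hat) {
  ord <- order(y_hat, decreasing = TRUE)
  ys <- y[ord]; ss <- y_hat[ord]
  tp <- cumsum(ys == 1L)
  fp <- cumsum(ys == 0L)
  # collapse tied scores: only the last index of each tie group is a
  # valid operating point
  last <- c(ss[-1L] != ss[-length(ss)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / sum(y == 1L)
  dr <- diff(c(0, rec))
  sum(dr * prec)
}

#' Aggregate per-fold metrics into a cross-validation report
#'
#' @param per_fold data.frame with one row per fold and columns
#'   ACC, MCC, AUC, AUPR.
#' @return object of class `m6a_metrics_report` with `per_fold`, `mean`
#'   and `sd` (sample standard deviation over folds).
#' @export
metrics_report <- function(per_fold) {
  cols <- c("ACC", "MCC", "AUC", "AUPR")
  out <- list(per_fold = per_fold,
              mean = vapply(per_fold[cols], mean, numeric(1)),
              sd = vapply(per_fold[cols], sd, numeric(1)),
              n_folds = nrow(per_fold))
  class(out) <- "m6a_metrics_report"
  out
}

#' @export
print.m6a_metrics_report <- function(x, ...) {
  cat(x$n_folds, "-fold cross-validation (mean ± sd)\n", sep = "")
  for (m in names(x$mean))
    cat(sprintf("  %-5s %.4f ± %.4f\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}

#' Write a metrics report as TSV and JSON
#'
#' @param report an `m6a_metrics_report`.
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return the two paths, invisibly.
#' @export
write_metrics_report <- function(report, prefix) {
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  df <- report$per_fold
  df <- rbind(df,
              data.frame(fold = "mean", t(report$mean)),
              data.frame(fold = "sd", t(report$sd)))
  write.table(format(df, digits = 4), tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(per_fold = report$per_fold,
                            mean = as.list(report$mean),
                            sd = as.list(report$sd)),
                       json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, json))
}
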