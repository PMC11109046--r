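#' Confusion matrix of true versus predicted stages
#'
#' @param true_stages,predicted_stages Equal-length vectors of stage
#'   labels in `1..n_stages`.
#' @param n_stages Number of stages (default 4).
#' @return An `n_stages x n_stages` integer matrix of class
#'   `cvm_confusion`; rows are true stages, columns predicted stages.
#' @export
confusion_matrix <- function(true_stages, predicted_stages, n_stages = 4) {
  if (length(true_stages) != length(predicted_stages)) {
    stop("true and predicted stage vectors differ in length",
         call. = FALSE)
  }
  lv <- seq_len(n_stages)
  bad <- c(setdiff(true_stages, lv), setdiff(predicted_stages, lv))
  if (length(bad)) {
    stop("stage label(s) outside 1..", n_stages, ": ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  cm <- table(factor(true_stages, levels = lv),
              factor(predicted_stages, levels = lv))
  cm <- matrix(as.integer(cm), n_stages, n_stages,
               dimnames = list(true = paste0("iCS", lv),
                               predicted = paste0("iCS", lv)))
  structure(cm, class = c("cvm_confusion", class(cm)))
}

#' @export
print.cvm_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = true stage, columns = predicted):\n")
  print(unclass(x))
  invisible(x)
}

#' Harmonic mean of precision and recall
#'
#' `F1 = 2 * P * R / (P + R)`; symmetric in its arguments. Returns `NA`
#' when either input is `NA`, and 0 when both are 0 by convention of the
#' limit.
#'
#' @param precision,recall Numeric vectors in \[0, 1\].
#' @return F1 score(s).
#' @export
f1_score <- function(precision, recall) {
  ifelse(is.na(precision) | is.na(recall), NA_real_,
         ifelse(precision + recall == 0, 0,
                2 * precision * recall / (precision + recall)))
}

#' Per-stage one-vs-rest precision, recall and F1
#'
#' For each stage, `TP` is the diagonal cell, `FP` the rest of its
#' column, `FN` the rest of its row; `precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)`, F1 their harmonic mean. A 0/0 ratio is
#' reported as `NA` ("undefined"), never coerced to 0 or 1. The
#' per-stage true-negative count is reported for completeness but feeds
#' no headline metric.
#'
#' @param cm A `cvm_confusion` (or plain square matrix).
#' @param stage Optional single stage; default all stages.
#' @return Data frame: `stage`, `tp`, `fp`, `fn`, `tn`, `precision`,
#'   `recall`, `f1`.
#' @export
per_stage_metrics <- function(cm, stage = NULL) {
  cm <- unclass(cm)
  stopifnot(nrow(cm) == ncol(cm))
  stages <- if (is.null(stage)) seq_len(nrow(cm)) else stage
  total <- sum(cm)
  out <- do.call(rbind, lapply(stages, function(s) {
    tp <- cm[s, s]
    fp <- sum(cm[, s]) - tp
    fn <- sum(cm[s, ]) - tp
    tn <- total - tp - fp - fn
    prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    data.frame(stage = s, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = prec, recall = rec,
               f1 = f1_score(prec, rec))
  }))
  rownames(out) <- NULL
  out
}

#' Overall multiclass accuracy
#'
#' `trace(cm) / sum(cm)`: the fraction of all subjects whose predicted
#' stage equals the true stage. This is the multiclass reading of the
#' usual `(TP+TN)/(TP+TN+FP+FN)` definition — summed over classes the
#' per-class TN contributions cancel, leaving the trace.
#'
#' @param cm Confusion matrix.
#' @return Fraction in \[0, 1\].
#' @export
accuracy <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix: accuracy undefined",
                       call. = FALSE)
  sum(diag(cm)) / total
}

#' Evaluate predicted stages against the truth
#'
#' Builds the confusion matrix and computes per-stage precision/recall/F1
#' (one-vs-rest), overall accuracy, macro averages (mean of the defined
#' per-stage values) and the micro average (= accuracy for single-label
#' multiclass).
#'
#' @param true_stages,predicted_stages Stage label vectors in `1..4`.
#' @param n_stages Number of stages (default 4).
#' @return Object of class `cvm_metrics`: list with `confusion`,
#'   `per_stage`, `accuracy`, `macro_precision`, `macro_recall`,
#'   `macro_f1`, `micro_f1`, `n`.
#' @export
evaluate <- function(true_stages, predicted_stages, n_stages = 4) {
  cm <- confusion_matrix(true_stages, predicted_stages, n_stages)
  ps <- per_stage_metrics(cm)
  structure(
    list(confusion = cm, per_stage = ps, accuracy = accuracy(cm),
         macro_precision = mean(ps$precision, na.rm = TRUE),
         macro_recall = mean(ps$recall, na.rm = TRUE),
         macro_f1 = mean(ps$f1, na.rm = TRUE),
         micro_f1 = accuracy(cm),
         n = sum(cm)),
    class = "cvm_metrics"
  )
}

#' @export
print.cvm_metrics <- function(x, ...) {
  print(x$confusion)
  cat("\nPer-stage metrics (one-vs-rest):\n")
  tab <- x$per_stage
  tab$precision <- sprintf("%.4f", tab$precision)
  tab$recall <- sprintf("%.4f", tab$recall)
  tab$f1 <- sprintf("%.4f", tab$f1)
  print(tab[, c("stage", "precision", "recall", "f1")], row.names = FALSE)
  cat(sprintf("\nOverall accuracy: %.4f (%.2f%%), n = %d\n",
              x$accuracy, 100 * x$accuracy, x$n))
  cat(sprintf("Macro precision/recall/F1: %.4f / %.4f / %.4f\n",
              x$macro_precision, x$macro_recall, x$macro_f1))
  invisible(x)
}

#' @export
plot.cvm_metrics <- function(x, main = "Confusion matrix", ...) {
  cm <- unclass(x$confusion)
  n <- nrow(cm)
  graphics::image(seq_len(n), seq_len(n), t(cm[n:1, ]),
                  col = grDevices::hcl.colors(32, "Blues", rev = TRUE),
                  axes = FALSE, xlab = "Predicted stage",
                  ylab = "True stage", main = main, ...)
  graphics::axis(1, at = seq_len(n), labels = colnames(cm))
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(cm)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    graphics::text(j, n + 1 - i, cm[i, j])
  }
  invisible(x)
}
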