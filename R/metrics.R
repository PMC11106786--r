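# From-scratch evaluation suite: stratified splits and k-fold, confusion
# matrices, classification reports, rank-based ROC-AUC with tie
# half-credit, Cohen's kappa and the Matthews correlation coefficient.
# Class order is fixed: normal first, tinnitus second; tinnitus is the
# positive class for AUC/MCC.

#' Stratified train/test split
#'
#' Per-class test counts are `round(class n x fraction)` with a
#' largest-remainder correction so the total equals
#' `round(n x fraction)`; assignment within class is a seeded uniform draw.
#'
#' @param labels Label vector (defines stratification).
#' @param test_fraction Fraction reserved for testing, in (0, 1).
#' @param stratified Stratify by label (default) or split at random.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(labels, test_fraction = 0.30,
                             stratified = TRUE, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort_config("test_fraction", "must lie in (0, 1)")
  }
  n <- length(labels)
  target <- floor(n * test_fraction + 0.5)
  with_seed(derive_seed(seed, "split"), {
    if (!stratified) {
      test <- sort(sample.int(n, target))
      return(list(train = setdiff(seq_len(n), test), test = test))
    }
    classes <- unique(labels)
    raw <- vapply(classes, function(cl) sum(labels == cl) * test_fraction, 1)
    counts <- floor(raw + 0.5)
    diff <- target - sum(counts)
    if (diff != 0) {
      # largest-remainder correction toward the global target
      rem <- raw - floor(raw)
      ord <- order(if (diff > 0) -rem else rem, seq_along(classes))
      for (i in ord[seq_len(abs(diff))]) {
        counts[i] <- counts[i] + sign(diff)
      }
    }
    test <- unlist(lapply(seq_along(classes), function(i) {
      idx <- which(labels == classes[i])
      idx[sample.int(length(idx), counts[i])]
    }))
    test <- sort(test)
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' Stratified k-fold assignment
#'
#' Shuffles each class and deals it round-robin over folds, so per-fold
#' class counts differ by at most one.
#'
#' @param labels Label vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id (1..k) per observation.
#' @export
stratified_kfold <- function(labels, k = 5, seed = 1L) {
  tabs <- table(labels)
  if (any(tabs < k)) {
    abort(sprintf("every class needs at least k = %d members", k),
          class = "audiodx_cv_error")
  }
  folds <- integer(length(labels))
  with_seed(derive_seed(seed, "kfold"), {
    for (cl in names(tabs)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Two-class confusion matrix
#'
#' Rows are actual classes, columns predicted, in fixed order (normal
#' first).
#'
#' @param y_true,y_pred Label vectors (`"normal"`/`"tinnitus"` or 0/1).
#' @param classes Class order.
#' @return An `aud_confusion` matrix of counts.
#' @export
confusion <- function(y_true, y_pred, classes = LABEL_LEVELS) {
  to_chr <- function(y) {
    if (is.numeric(y) && all(y %in% c(0, 1))) classes[y + 1] else as.character(y)
  }
  y_true <- to_chr(y_true); y_pred <- to_chr(y_pred)
  if (length(y_true) != length(y_pred)) {
    abort("y_true and y_pred must have equal length",
          class = "audiodx_metric_error")
  }
  bad <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(bad) > 0) {
    abort(paste("unknown labels:", paste(bad, collapse = ", ")),
          class = "audiodx_metric_error")
  }
  m <- matrix(0L, 2, 2, dimnames = list(actual = classes, predicted = classes))
  for (i in seq_along(y_true)) {
    m[y_true[i], y_pred[i]] <- m[y_true[i], y_pred[i]] + 1L
  }
  structure(m, class = c("aud_confusion", "matrix", "array"))
}

#' Build a confusion matrix directly from counts
#'
#' @param normal_normal,normal_tinnitus Counts in the actual-normal row.
#' @param tinnitus_normal,tinnitus_tinnitus Counts in the actual-tinnitus
#'   row.
#' @return An `aud_confusion` matrix.
#' @export
confusion_from_counts <- function(normal_normal, normal_tinnitus,
                                  tinnitus_normal, tinnitus_tinnitus) {
  m <- matrix(as.integer(c(normal_normal, tinnitus_normal,
                           normal_tinnitus, tinnitus_tinnitus)), 2, 2,
              dimnames = list(actual = LABEL_LEVELS,
                              predicted = LABEL_LEVELS))
  if (any(m < 0)) abort("counts must be non-negative",
                        class = "audiodx_metric_error")
  structure(m, class = c("aud_confusion", "matrix", "array"))
}

safe_div <- function(num, den) {
  flagged <- den == 0
  out <- ifelse(flagged, 0, num / ifelse(flagged, 1, den))
  attr(out, "zero_division") <- flagged
  out
}

#' Per-class classification report from a confusion matrix
#'
#' Precision, recall, F1 and support per class, plus accuracy and macro /
#' support-weighted averages, mirroring the standard text classification
#' report. Zero denominators yield 0 with a flag.
#'
#' @param cm An `aud_confusion` matrix.
#' @return An `aud_report` list: `per_class` tibble, `accuracy`,
#'   `macro_avg`, `weighted_avg`, `n`, `zero_division` flag.
#' @export
#' @examples
#' classification_report(confusion_from_counts(162, 9, 14, 118))
classification_report <- function(cm) {
  if (!inherits(cm, "aud_confusion")) cm <- as_confusion(cm)
  if (sum(cm) == 0) abort("empty confusion matrix",
                          class = "audiodx_metric_error")
  classes <- rownames(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  correct <- diag(cm)
  precision <- safe_div(correct, predicted)
  recall <- safe_div(correct, support)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  zero_flag <- any(attr(precision, "zero_division"),
                   attr(recall, "zero_division"),
                   attr(f1, "zero_division"))
  per_class <- tibble(class = classes,
                      precision = as.numeric(precision),
                      recall = as.numeric(recall),
                      f1 = as.numeric(f1),
                      support = as.numeric(support))
  wmean <- function(v) sum(v * support) / sum(support)
  structure(list(
    per_class = per_class,
    accuracy = sum(correct) / sum(cm),
    macro_avg = c(precision = mean(per_class$precision),
                  recall = mean(per_class$recall),
                  f1 = mean(per_class$f1)),
    weighted_avg = c(precision = wmean(per_class$precision),
                     recall = wmean(per_class$recall),
                     f1 = wmean(per_class$f1)),
    n = sum(cm), zero_division = isTRUE(zero_flag)),
    class = "aud_report")
}

as_confusion <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == 2, ncol(m) == 2)
  confusion_from_counts(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
}

#' @export
print.aud_report <- function(x, digits = 2, ...) {
  fm <- function(v) formatC(v, digits = digits, format = "f")
  cat(sprintf("%12s %9s %9s %9s %9s\n", "", "precision", "recall",
              "f1-score", "support"))
  for (i in seq_len(nrow(x$per_class))) {
    r <- x$per_class[i, ]
    cat(sprintf("%12s %9s %9s %9s %9d\n", r$class, fm(r$precision),
                fm(r$recall), fm(r$f1), as.integer(r$support)))
  }
  cat(sprintf("%12s %9s %9s %9s %9d\n", "accuracy", "", "",
              fm(x$accuracy), x$n))
  cat(sprintf("%12s %9s %9s %9s %9d\n", "macro avg",
              fm(x$macro_avg["precision"]), fm(x$macro_avg["recall"]),
              fm(x$macro_avg["f1"]), x$n))
  cat(sprintf("%12s %9s %9s %9s %9d\n", "weighted avg",
              fm(x$weighted_avg["precision"]), fm(x$weighted_avg["recall"]),
              fm(x$weighted_avg["f1"]), x$n))
  invisible(x)
}

#' @export
tidy.aud_report <- function(x, ...) x$per_class

#' @export
glance.aud_report <- function(x, ...) {
  tibble(accuracy = x$accuracy,
         macro_f1 = unname(x$macro_avg["f1"]),
         weighted_f1 = unname(x$weighted_avg["f1"]), n = x$n)
}

#' Rank-based ROC-AUC with tie half-credit
#'
#' The Mann-Whitney statistic: the probability that a random positive
#' scores above a random negative, counting ties as one half. A constant
#' score vector therefore yields exactly 0.5.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (tinnitus/1 = positive).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    abort("both classes must be present", class = "audiodx_metric_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Sweeps the decision threshold over the distinct scores, returning
#' monotone (FPR, TPR) pairs from (0, 0) to (1, 1).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @return An `aud_roc` tibble: `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    abort("both classes must be present", class = "audiodx_metric_error")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- purrr::map(thr, function(t) {
    pred <- scores >= t
    tibble(threshold = t, fpr = sum(pred & y == 0) / n0,
           tpr = sum(pred & y == 1) / n1)
  })
  out <- bind_rows(tibble(threshold = Inf, fpr = 0, tpr = 0), bind_rows(pts))
  if (out$fpr[nrow(out)] < 1 || out$tpr[nrow(out)] < 1) {
    out <- bind_rows(out, tibble(threshold = -Inf, fpr = 1, tpr = 1))
  }
  structure(out, class = c("aud_roc", class(out)))
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement: `(p_o - p_e) / (1 - p_e)`; a zero
#' denominator yields 0 with a flag.
#'
#' @param cm An `aud_confusion` matrix.
#' @return Kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(cm) {
  if (!inherits(cm, "aud_confusion")) cm <- as_confusion(cm)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (1 - pe == 0) return(structure(0, zero_division = TRUE))
  (po - pe) / (1 - pe)
}

#' Matthews correlation coefficient from a confusion matrix
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` with tinnitus as
#' the positive class; a zero denominator yields 0 with a flag.
#'
#' @param cm An `aud_confusion` matrix.
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(cm) {
  if (!inherits(cm, "aud_confusion")) cm <- as_confusion(cm)
  tp <- cm[2, 2]; tn <- cm[1, 1]; fp <- cm[1, 2]; fn <- cm[2, 1]
  den <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  if (den == 0) return(structure(0, zero_division = TRUE))
  (tp * tn - fp * fn) / den
}

#' Full diagnostic metrics report
#'
#' Combines the confusion matrix, classification report, rank-based AUC,
#' Cohen's kappa, MCC and ROC points for one evaluated classifier.
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels.
#' @param scores Optional positive-class scores (enables AUC/ROC).
#' @return An `aud_metrics` list.
#' @export
metrics_report <- function(y_true, y_pred, scores = NULL) {
  cm <- confusion(y_true, y_pred)
  rep <- classification_report(cm)
  auc <- NULL; roc <- NULL
  if (!is.null(scores)) {
    auc <- roc_auc(scores, y_true)
    roc <- roc_points(scores, y_true)
  }
  structure(list(confusion = cm, report = rep, auc = auc,
                 kappa = as.numeric(cohen_kappa(cm)),
                 mcc = as.numeric(mcc(cm)), roc = roc),
            class = "aud_metrics")
}

#' @export
print.aud_metrics <- function(x, ...) {
  cat("confusion matrix (rows = actual):\n")
  print(unclass(x$confusion))
  cat("\n")
  print(x$report)
  if (!is.null(x$auc)) cat(sprintf("\nAUC   %.4f\n", x$auc))
  cat(sprintf("kappa %.4f\nMCC   %.4f\n", x$kappa, x$mcc))
  invisible(x)
}

#' @export
glance.aud_metrics <- function(x, ...) {
  tibble(accuracy = x$report$accuracy,
         auc = x$auc %||% NA_real_, kappa = x$kappa, mcc = x$mcc,
         n = x$report$n)
}

#' Serialize a metrics report to JSON
#'
#' Full precision is retained in the JSON; the printed report rounds to two
#' decimals.
#'
#' @param metrics An `aud_metrics` object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  ser <- list(confusion = unclass(metrics$confusion),
              per_class = metrics$report$per_class,
              accuracy = metrics$report$accuracy,
              macro_avg = as.list(metrics$report$macro_avg),
              weighted_avg = as.list(metrics$report$weighted_avg),
              auc = metrics$auc, kappa = metrics$kappa, mcc = metrics$mcc)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
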