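#' Multiclass confusion matrix with one-vs-rest collapse
#'
#' `matrix[i, j]` counts samples with true class `i` predicted as `j`.
#' Per-class one-vs-rest counts (TP, FN, FP, TN) are derived for each class.
#'
#' @param truth,pred Equal-length label vectors from one scheme.
#' @param levels Class levels; defaults to the sorted union of the observed
#'   labels. Labels outside `levels` are an error.
#' @return An `mf_confusion`: list with `table` (the multiclass matrix) and
#'   `by_class` (tibble `class`, `tp`, `fn`, `fp`, `tn`).
#' @export
confusion_matrix <- function(truth, pred, levels = NULL) {
  if (length(truth) != length(pred)) {
    abort("`truth` and `pred` must have equal length")
  }
  truth <- as.character(truth)
  pred <- as.character(pred)
  levels <- levels %||% sort(unique(c(truth, pred)))
  bad <- setdiff(unique(c(truth, pred)), levels)
  if (length(bad) > 0) {
    abort(sprintf("label(s) outside the scheme: %s",
                  paste(bad, collapse = ", ")))
  }
  tab <- table(
    truth = factor(truth, levels = levels),
    pred = factor(pred, levels = levels)
  )
  m <- unclass(tab)
  total <- sum(m)
  by_class <- dplyr::bind_rows(purrr::map(seq_along(levels), function(i) {
    tp <- m[i, i]
    fn <- sum(m[i, ]) - tp
    fp <- sum(m[, i]) - tp
    tibble(class = levels[i], tp = tp, fn = fn, fp = fp,
           tn = total - tp - fn - fp)
  }))
  structure(list(table = m, by_class = by_class), class = "mf_confusion")
}

#' @export
print.mf_confusion <- function(x, ...) {
  cat("<mf_confusion>\n")
  print(x$table)
  invisible(x)
}

#' @rdname confusion_matrix
#' @param x An `mf_confusion`.
#' @param ... Unused.
#' @export
tidy.mf_confusion <- function(x, ...) x$by_class

#' @rdname confusion_matrix
#' @export
glance.mf_confusion <- function(x, ...) {
  tibble(
    n = sum(x$table),
    correct = sum(diag(x$table)),
    accuracy = overall_accuracy(diag(x$table), rowSums(x$table))
  )
}

#' Binary performance metrics from confusion counts
#'
#' Sensitivity `100 TP / (TP + FN)`, specificity `100 TN / (TN + FP)`,
#' precision `100 TP / (TP + FP)` and accuracy `100 (TP + TN) / total`.
#' A zero denominator yields `NA` (undefined, never 0) with a warning.
#'
#' @param tp Either the TP count, or a data frame with columns
#'   `tp`, `fn`, `fp`, `tn` (e.g. the `by_class` table of an
#'   `mf_confusion`), in which case the remaining arguments are ignored.
#' @param fn,fp,tn Counts (scalars or vectors).
#' @param digits Round metrics to this many decimals (default 2, the printed
#'   precision); `NULL` keeps full precision.
#' @return A tibble with columns `sensitivity`, `specificity`, `precision`,
#'   `accuracy` (percent), preceded by any identifier columns of a data-frame
#'   input.
#' @export
binary_metrics <- function(tp, fn = NULL, fp = NULL, tn = NULL, digits = 2) {
  if (is.data.frame(tp)) {
    counts <- tp
    ids <- counts[setdiff(names(counts), c("tp", "fn", "fp", "tn"))]
    tp <- counts$tp; fn <- counts$fn; fp <- counts$fp; tn <- counts$tn
  } else {
    ids <- NULL
  }
  if (any(c(tp, fn, fp, tn) < 0)) abort("counts must be nonnegative")
  if (any(tp + fn + fp + tn == 0)) abort("total count must be positive")
  rate <- function(num, den, what) {
    out <- ifelse(den > 0, 100 * num / den, NA_real_)
    if (anyNA(out)) {
      warn(sprintf("%s undefined (zero denominator); reported as NA", what))
    }
    out
  }
  out <- tibble(
    sensitivity = rate(tp, tp + fn, "sensitivity"),
    specificity = rate(tn, tn + fp, "specificity"),
    precision = rate(tp, tp + fp, "precision"),
    accuracy = 100 * (tp + tn) / (tp + fn + fp + tn)
  )
  if (!is.null(digits)) out <- dplyr::mutate(out, dplyr::across(
    dplyr::everything(), ~ round(.x, digits)
  ))
  if (!is.null(ids) && ncol(ids) > 0) out <- dplyr::bind_cols(ids, out)
  out
}

#' Overall classification accuracy from per-class counts
#'
#' `100 * sum(correct) / sum(tested)`, reported to one decimal (the printed
#' precision); use `digits = NULL` for full precision.
#'
#' @param correct,tested Per-class correctly-classified and tested counts.
#' @param digits Decimals to round to (default 1); `NULL` for full precision.
#' @return Accuracy in percent.
#' @export
overall_accuracy <- function(correct, tested, digits = 1) {
  if (length(correct) != length(tested)) {
    abort("`correct` and `tested` must have equal length")
  }
  if (any(correct < 0) || any(tested < 0) || any(correct > tested)) {
    abort("need 0 <= correct <= tested per class")
  }
  if (sum(tested) == 0) abort("no tested samples")
  acc <- 100 * sum(correct) / sum(tested)
  if (is.null(digits)) acc else round(acc, digits)
}

#' One-vs-rest ROC curve and AUC
#'
#' Sweeps a threshold over the distinct scores in descending order (tied
#' scores form a single step), collecting (FPR, TPR) points anchored at
#' (0, 0) and (1, 1); the AUC is the trapezoid-rule area.
#'
#' @param scores Per-sample score for the target class (e.g. KNN vote
#'   fraction).
#' @param labels Logical (or coercible) one-vs-rest truth: `TRUE` = target
#'   class. Both classes must be present.
#' @return An `mf_roc`: tibble with columns `threshold`, `fpr`, `tpr` and
#'   attribute `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal length")
  }
  if (anyNA(scores) || anyNA(labels)) abort("missing scores or labels")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) abort("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  block_end <- which(c(diff(s) != 0, TRUE)) # index ending each tied block
  tpr <- c(0, cumsum(l)[block_end] / n_pos, 1)
  fpr <- c(0, cumsum(!l)[block_end] / n_neg, 1)
  thr <- c(Inf, s[block_end], -Inf)
  pts <- tibble(threshold = thr, fpr = fpr, tpr = tpr)
  pts <- dplyr::distinct(pts, .data$fpr, .data$tpr, .keep_all = TRUE)
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  out <- tibble::new_tibble(pts, class = "mf_roc")
  attr(out, "auc") <- auc
  out
}

#' @rdname roc_curve
#' @return `roc_auc()`: the AUC as a single number.
#' @export
roc_auc <- function(scores, labels) {
  attr(roc_curve(scores, labels), "auc")
}
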