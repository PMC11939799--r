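# Confusion matrix and agreement metrics (accuracy, per-class
# precision/recall/F1, macro-F1, Cohen's kappa).

#' Confusion matrix
#'
#' Counts of (expert label, predicted label) pairs on a fixed class order;
#' rows are the reference labels, columns the predictions.
#'
#' @param truth,estimate label vectors of equal length.
#' @param levels class order; defaults to the five-stage alphabet.
#' @return integer matrix with `levels` as dimnames.
#' @export
confusion_matrix <- function(truth, estimate, levels = stage_levels()) {
  stopifnot(length(truth) == length(estimate))
  bad <- setdiff(unique(c(as.character(truth), as.character(estimate))), levels)
  if (length(bad) > 0L) {
    stop("labels outside the class alphabet: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  t_f <- factor(truth, levels = levels)
  e_f <- factor(estimate, levels = levels)
  unclass(table(truth = t_f, predicted = e_f))
}

#' Overall accuracy of a confusion matrix
#'
#' Fraction of epochs on the diagonal, in percent.
#'
#' @param cm square count matrix (rows = truth).
#' @return percent in \[0, 100\].
#' @export
cm_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  100 * sum(diag(cm)) / total
}

#' Per-class precision, recall and F1
#'
#' One-vs-rest metrics per class, in percent: precision = TP / (TP + FP)
#' (column-wise), recall = TP / (TP + FN) (row-wise), F1 their harmonic
#' mean. A zero denominator yields 0.
#'
#' @param cm square count matrix (rows = truth).
#' @return tibble `class`, `precision`, `recall`, `f1` (percent).
#' @export
per_class_metrics <- function(cm) {
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  tibble::tibble(
    class = rownames(cm) %||% as.character(seq_len(nrow(cm))),
    precision = unname(100 * prec),
    recall = unname(100 * rec),
    f1 = unname(100 * f1)
  )
}

#' Macro-averaged F1
#'
#' Unweighted mean of the per-class F1 scores, in percent.
#'
#' @param cm square count matrix.
#' @return percent.
#' @export
macro_f1 <- function(cm) mean(per_class_metrics(cm)$f1)

#' Cohen's kappa
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with
#' \eqn{p_o} the observed accuracy and
#' \eqn{p_e = \sum_c (\mathrm{row}_c \cdot \mathrm{col}_c) / n^2} the
#' marginal chance agreement.
#'
#' @param cm square count matrix.
#' @return kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  p_o <- sum(diag(cm)) / total
  p_e <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (p_e >= 1) stop("degenerate marginals: chance agreement is 1", call. = FALSE)
  (p_o - p_e) / (1 - p_e)
}

#' Evaluate a staging prediction
#'
#' Bundles the confusion matrix with all agreement metrics.
#'
#' @param truth,estimate label vectors, or a pre-computed confusion matrix
#'   passed as `truth` with `estimate` missing.
#' @param levels class order.
#' @return object of class `stage_eval`: list with `cm`, `per_class`
#'   (tibble), `accuracy`, `macro_f1`, `kappa`, `n`.
#' @export
evaluate_staging <- function(truth, estimate = NULL, levels = stage_levels()) {
  cm <- if (is.null(estimate)) as.matrix(truth)
        else confusion_matrix(truth, estimate, levels)
  structure(
    list(cm = cm, per_class = per_class_metrics(cm),
         accuracy = cm_accuracy(cm), macro_f1 = macro_f1(cm),
         kappa = cohen_kappa(cm), n = sum(cm)),
    class = "stage_eval"
  )
}

#' @export
print.stage_eval <- function(x, ...) {
  cat("Staging evaluation on ", x$n, " epochs\n", sep = "")
  print(x$cm)
  cat(sprintf("accuracy %.2f%%  macro-F1 %.2f  kappa %.3f\n",
              x$accuracy, x$macro_f1, x$kappa))
  invisible(x)
}

#' @export
tidy.stage_eval <- function(x, ...) x$per_class

#' @export
glance.stage_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, macro_f1 = x$macro_f1,
                 kappa = x$kappa, n = x$n)
}
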