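#' Multiclass confusion matrix
#'
#' @param truth,predicted Integer vectors of 0-based class labels.
#' @param n_classes Number of classes.
#' @return An `n_classes x n_classes` integer matrix, rows = true class,
#'   columns = predicted class.
#' @export
confusion_matrix <- function(truth, predicted, n_classes) {
  stopifnot(length(truth) == length(predicted))
  counts <- matrix(0L, n_classes, n_classes,
                   dimnames = list(true = 0:(n_classes - 1),
                                   pred = 0:(n_classes - 1)))
  for (i in seq_along(truth)) {
    counts[truth[i] + 1L, predicted[i] + 1L] <-
      counts[truth[i] + 1L, predicted[i] + 1L] + 1L
  }
  counts
}

#' Cohen's kappa from a confusion matrix
#'
#' The default is standard Cohen's kappa, `(Po - Pe) / (1 - Pe)` with the
#' observed agreement `Po = trace / N` and the chance agreement `Pe`
#' computed from the row and column marginals.  `variant = "per_class"`
#' instead averages one-vs-rest binary kappas over the classes (a reading
#' of the per-class-summed form sometimes printed in the BCI literature);
#' it is provided for comparison and is not the default.
#'
#' @param counts Confusion matrix (rows = true, cols = predicted).
#' @param variant `"cohen"` (default) or `"per_class"`.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(counts, variant = c("cohen", "per_class")) {
  variant <- match.arg(variant)
  N <- sum(counts)
  if (N == 0) stop("empty confusion matrix", call. = FALSE)
  binary_kappa <- function(cm) {
    po <- sum(diag(cm)) / sum(cm)
    pe <- sum(rowSums(cm) * colSums(cm)) / sum(cm)^2
    if (abs(1 - pe) < 1e-12) return(0)
    (po - pe) / (1 - pe)
  }
  if (variant == "cohen") {
    po <- sum(diag(counts)) / N
    pe <- sum(rowSums(counts) * colSums(counts)) / N^2
    if (abs(1 - pe) < 1e-12) return(if (po >= 1 - 1e-12) 1 else 0)
    (po - pe) / (1 - pe)
  } else {
    nc <- nrow(counts)
    mean(vapply(seq_len(nc), function(o) {
      tp <- counts[o, o]
      fn <- sum(counts[o, ]) - tp
      fp <- sum(counts[, o]) - tp
      tn <- N - tp - fn - fp
      binary_kappa(matrix(c(tp, fp, fn, tn), 2, 2))
    }, numeric(1)))
  }
}

#' Evaluate a fitted model on a test set
#'
#' Predicts by argmax over class probabilities (ties broken toward the
#' lowest class index), fills the confusion matrix, and reports overall
#' accuracy (`trace / N`), Cohen's kappa, and per-class accuracy.
#'
#' @param model A fitted `mi_model`.
#' @param epochs_test An [epoch_set()]; must be non-empty.
#' @param kappa_variant Passed to [cohen_kappa()].
#' @return An object of class `mi_metrics` with fields `accuracy`, `kappa`,
#'   `per_class_accuracy`, `confusion`, `n`.
#' @export
evaluate <- function(model, epochs_test, kappa_variant = "cohen") {
  if (length(epochs_test$labels) == 0L) {
    stop("empty test set", call. = FALSE)
  }
  pred <- predict.mi_model(model, epochs_test, type = "class")
  metrics_from_predictions(epochs_test$labels, pred,
                           model$cfg$n_classes, kappa_variant)
}

metrics_from_predictions <- function(truth, pred, n_classes,
                                     kappa_variant = "cohen") {
  counts <- confusion_matrix(truth, pred, n_classes)
  per_class <- diag(counts) / pmax(rowSums(counts), 1L)
  per_class[rowSums(counts) == 0L] <- NA_real_
  structure(list(
    accuracy = sum(diag(counts)) / sum(counts),
    kappa = cohen_kappa(counts, kappa_variant),
    per_class_accuracy = per_class,
    confusion = counts,
    n = sum(counts)
  ), class = "mi_metrics")
}

#' @export
print.mi_metrics <- function(x, ...) {
  cat(sprintf("<mi_metrics> n = %d  accuracy = %.4f  kappa = %.4f\n",
              x$n, x$accuracy, x$kappa))
  print(x$confusion)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.mi_metrics <- function(x, ...) {
  tibble::tibble(
    class = seq_along(x$per_class_accuracy) - 1L,
    n = rowSums(x$confusion),
    correct = diag(x$confusion),
    accuracy = x$per_class_accuracy
  )
}

#' @importFrom generics glance
#' @export
glance.mi_metrics <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy, kappa = x$kappa)
}
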