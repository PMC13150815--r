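# PLS discriminant analysis on a 0/1 dummy response, plus threshold-free
# classification metrics.

#' Fit a PLS-DA model
#'
#' PLS1 regression on a 0/1 dummy coding of the two classes (positive class =
#' 1). The default decision rule thresholds the predicted dummy value at 0.5;
#' "probabilities" are the raw dummy predictions clipped to [0, 1] and are
#' reported as such, not as calibrated posteriors.
#'
#' @param X predictor matrix.
#' @param labels logical vector (or 2-level factor / 0-1 numeric); `TRUE` (or
#'   the second factor level, or 1) is the positive class.
#' @param n_lv number of latent variables.
#' @param threshold decision threshold in (0, 1), default 0.5.
#' @return object of class `plsda_model` wrapping the underlying `pls_model`.
#' @export
fit_plsda <- function(X, labels, n_lv, threshold = 0.5) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("training set contains a single class", call. = FALSE)
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)", call. = FALSE)
  model <- fit_pls(X, y, n_lv)
  structure(list(model = model, threshold = threshold,
                 classes = c(negative = 0, positive = 1)),
            class = "plsda_model")
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.numeric(labels))
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("labels must have exactly 2 levels", call. = FALSE)
    return(as.numeric(labels == levels(labels)[2]))
  }
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) stop("numeric labels must be 0/1", call. = FALSE)
  y
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d latent variable(s), threshold %.2f\n",
              x$model$n_lv, x$threshold))
  invisible(x)
}

#' Predict class "probability" (clipped dummy prediction)
#'
#' @param model a `plsda_model`.
#' @param newdata predictor matrix.
#' @param n_lv optional LV count (default: all fitted).
#' @return numeric vector in [0, 1].
#' @export
predict_proba <- function(model, newdata, n_lv = NULL) {
  pmin(pmax(predict(model$model, newdata, n_lv = n_lv), 0), 1)
}

#' Classify samples with a fitted PLS-DA model
#'
#' @inheritParams predict_proba
#' @return logical vector (`TRUE` = positive class).
#' @export
classify <- function(model, newdata, n_lv = NULL) {
  predict(model$model, newdata, n_lv = n_lv) >= model$threshold
}

#' Area under the ROC curve (Mann-Whitney concordance)
#'
#' The probability that a random positive scores above a random negative,
#' with ties counted one half; computed from midranks.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (see [fit_plsda()] for accepted encodings).
#' @return value in [0, 1].
#' @export
auroc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUROC needs both classes", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Misclassification fraction
#'
#' @param pred predicted labels (logical or 0/1).
#' @param labels reference labels.
#' @return fraction in [0, 1].
#' @export
classification_error <- function(pred, labels) {
  mean(as_binary_labels(pred) != as_binary_labels(labels))
}
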