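#' Confusion matrix for binary risk predictions
#'
#' The positive class is high risk (label 1) throughout: `tp` counts
#' correctly flagged high-risk subjects and `tn` correctly cleared low-risk
#' subjects.
#'
#' @param truth,estimate Equal-length vectors with entries in \{0, 1\}.
#' @return An object of class `confusion_matrix` with counts `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
#' @examples
#' confusion_matrix(c(1, 0, 1), c(1, 0, 0))
confusion_matrix <- function(truth, estimate) {
  if (length(truth) != length(estimate)) stop_shape("confusion_matrix: length mismatch")
  if (!all(truth %in% c(0, 1)) || !all(estimate %in% c(0, 1))) {
    stop_value("confusion_matrix: entries must be 0/1")
  }
  confusion_counts(tp = sum(truth == 1 & estimate == 1),
                   fp = sum(truth == 0 & estimate == 1),
                   tn = sum(truth == 0 & estimate == 0),
                   fn = sum(truth == 1 & estimate == 0))
}

#' @rdname confusion_matrix
#' @param tp,fp,tn,fn Non-negative counts, for building a confusion matrix
#'   directly from published numbers.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop_value("confusion counts must be non-negative")
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2,
              dimnames = list(predicted = c("low (0)", "high (1)"),
                              truth = c("low (0)", "high (1)")))
  print(m)
  invisible(x)
}

# Half-up rounding to `digits` decimals (R's round() is half-to-even).
round_half_up <- function(x, digits = 2) floor(x * 10^digits + 0.5) / 10^digits

#' Screening metrics from a confusion matrix
#'
#' Accuracy `(tp+tn)/n`, precision `tp/(tp+fp)`, recall (sensitivity)
#' `tp/(tp+fn)`, F1 (harmonic mean of precision and recall) and specificity
#' `tn/(tn+fp)`, with high risk as the positive class. Zero-denominator
#' cases are flagged undefined (`NA` with `defined = FALSE`), never silently
#' zero. Values are reported both exactly and rounded half-up to 2 decimals,
#' the convention used when comparing against published tables.
#'
#' @param cm A [confusion_matrix()] (or the result of [confusion_counts()]).
#' @return A tibble with columns `metric`, `value`, `rounded`, `defined`.
#' @export
#' @examples
#' screening_metrics(confusion_counts(tp = 20, fp = 0, tn = 18, fn = 1))
screening_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  if (total < 1) stop_value("screening_metrics: empty confusion matrix")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe_div(cm$tp, cm$tp + cm$fp)
  recall <- safe_div(cm$tp, cm$tp + cm$fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  vals <- c(accuracy = (cm$tp + cm$tn) / total,
            precision = precision, recall = recall, f1 = f1,
            specificity = safe_div(cm$tn, cm$tn + cm$fp))
  tibble::tibble(metric = names(vals),
                 value = unname(vals),
                 rounded = round_half_up(unname(vals), 2),
                 defined = !is.na(vals))
}

#' k-nearest-neighbour baseline
#'
#' Euclidean-distance majority vote over the `k` nearest training rows.
#' Ties in the vote break toward high risk (label 1), consistent with the
#' package's screening posture. Features should be pre-normalized.
#'
#' @param train A labelled tibble (features + `risk_label`).
#' @param newdata A feature tibble or numeric matrix to classify.
#' @param k Neighbourhood size (default 5); must be between 1 and
#'   `nrow(train)`.
#' @return Integer vector of 0/1 labels.
#' @export
knn_predict <- function(train, newdata, k = 5L) {
  if (k < 1) stop_config("knn_predict: k must be >= 1")
  if (k > nrow(train)) stop_config("knn_predict: k exceeds the training size")
  Xtr <- feature_matrix(train)
  y <- train$risk_label
  X <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  tr_sq <- rowSums(Xtr^2)
  vapply(seq_len(nrow(X)), function(i) {
    d2 <- tr_sq - 2 * drop(Xtr %*% X[i, ]) + sum(X[i, ]^2)
    nn <- order(d2)[seq_len(k)]
    votes1 <- sum(y[nn] == 1)
    as.integer(votes1 >= k - votes1) # tie -> high risk
  }, integer(1))
}

#' Evaluate a fitted model on a labelled test set
#'
#' Convenience wrapper: predict, cross-tabulate, compute the screening
#' metrics.
#'
#' @param fit A `samlp_fit`.
#' @param test A labelled tibble (standardized like the training data).
#' @return A list with `confusion` and `metrics` (see
#'   [screening_metrics()]).
#' @export
evaluate_model <- function(fit, test) {
  pred <- predict(fit, test, type = "class")
  cm <- confusion_matrix(test$risk_label, pred)
  list(confusion = cm, metrics = screening_metrics(cm))
}
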