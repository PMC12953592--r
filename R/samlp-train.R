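#' Train the SA-MLP risk classifier
#'
#' Mini-batch Adam on binary cross-entropy. A stratified `val_frac` share of
#' the training rows is carved out once (under a substream of the seed) to
#' monitor validation loss; training stops early after `patience` epochs
#' without improvement and the best-epoch weights are restored. Per-epoch
#' shuffling and dropout masks are seeded, so the same data and seed yield
#' an identical fit, history and predictions.
#'
#' Features are consumed as-is: standardize them first (see [zscore_fit()])
#' as the labelling thresholds live in raw units but the network trains on
#' z-scores.
#'
#' @param data A labelled tibble: numeric feature columns plus a binary
#'   `risk_label` column with both classes present.
#' @param config A [samlp_config()].
#' @param training A [train_config()].
#' @return An object of class `samlp_fit`: parameters, configs, an epoch
#'   history tibble (`epoch`, `train_loss`, `val_loss`), `best_epoch`,
#'   `stopped_epoch` and the feature-name contract for prediction.
#' @export
#' @examples
#' ds <- simulate_labeled_dataset(synth_params(n = 120, seed = 3, target_balance = 0.5))
#' std <- zscore_apply(ds, zscore_fit(ds))
#' fit <- samlp_train(std, training = train_config(epochs = 3, seed = 3))
#' glance(fit)
samlp_train <- function(data, config = samlp_config(), training = train_config()) {
  if (!"risk_label" %in% names(data)) stop_value("samlp_train: no risk_label column")
  if (length(unique(data$risk_label)) < 2) {
    abort("samlp_train: training data contains a single class",
          class = "voicerisk_training_error")
  }
  fc <- feature_columns(data)
  if (length(fc) != config$input_dim) {
    stop_shape(sprintf("data has %d features but config expects %d",
                       length(fc), config$input_dim))
  }

  if (training$val_frac > 0) {
    carve <- stratified_split(data, test_frac = training$val_frac,
                              seed = substream_seed(training$seed, "val-carveout"))
    fit_part <- carve$train
    val_part <- carve$test
  } else {
    fit_part <- data
    val_part <- NULL
  }
  X <- feature_matrix(fit_part)
  y <- fit_part$risk_label
  Xv <- if (!is.null(val_part)) feature_matrix(val_part)
  yv <- if (!is.null(val_part)) val_part$risk_label

  params <- init_params(config, seed = substream_seed(training$seed, "init"))
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- lapply(params, function(p) p * 0)
  t_step <- 0L
  n_fit <- nrow(X)
  monitor_es <- training$patience > 0

  history <- vector("list", training$epochs)
  best_loss <- Inf
  best_epoch <- 0L
  best_params <- params
  stale <- 0L
  stopped_epoch <- training$epochs

  set.seed(substream_seed(training$seed, "epochs"))
  for (epoch in seq_len(training$epochs)) {
    perm <- sample.int(n_fit)
    starts <- seq(1, n_fit, by = training$batch_size)
    for (s in starts) {
      idx <- perm[s:min(s + training$batch_size - 1, n_fit)]
      bp <- samlp_backprop(X[idx, , drop = FALSE], y[idx], params, config,
                           training = TRUE)
      t_step <- t_step + 1L
      for (nm in names(bp$grads)) {
        g <- bp$grads[[nm]]
        adam_m[[nm]] <- training$adam_beta1 * adam_m[[nm]] + (1 - training$adam_beta1) * g
        adam_v[[nm]] <- training$adam_beta2 * adam_v[[nm]] + (1 - training$adam_beta2) * g^2
        mhat <- adam_m[[nm]] / (1 - training$adam_beta1^t_step)
        vhat <- adam_v[[nm]] / (1 - training$adam_beta2^t_step)
        params[[nm]] <- params[[nm]] -
          training$learning_rate * mhat / (sqrt(vhat) + training$adam_eps)
      }
    }
    train_loss <- bce_loss(y, samlp_forward(X, params, config, training = FALSE))
    val_loss <- if (!is.null(val_part)) {
      bce_loss(yv, samlp_forward(Xv, params, config, training = FALSE))
    } else {
      train_loss
    }
    if (!is.finite(train_loss) || !is.finite(val_loss)) {
      abort(sprintf("training diverged at epoch %d (non-finite loss)", epoch),
            class = "voicerisk_numerical_error")
    }
    history[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = train_loss,
                                       val_loss = val_loss)
    if (val_loss < best_loss) {
      best_loss <- val_loss
      best_epoch <- epoch
      best_params <- params
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    if (monitor_es && stale >= training$patience) {
      stopped_epoch <- epoch
      break
    }
  }
  if (monitor_es) params <- best_params

  structure(list(params = params, config = config, training = training,
                 history = dplyr::bind_rows(history),
                 best_epoch = best_epoch, stopped_epoch = stopped_epoch,
                 best_val_loss = best_loss,
                 feature_names = fc,
                 n_train = n_fit,
                 n_val = if (is.null(val_part)) 0L else nrow(val_part)),
            class = "samlp_fit")
}

#' Plain-DNN baseline: the SA-MLP with the attention block removed
#'
#' Identical architecture and training path except that the first dense
#' layer's output feeds layer normalization directly (no Q/K/V/O
#' projections, no residual duplication). Its parameter count is the
#' SA-MLP's minus the four attention projections.
#'
#' @inheritParams samlp_train
#' @return A `samlp_fit` whose config has `use_attention = FALSE`.
#' @export
dnn_baseline <- function(data, config = samlp_config(use_attention = FALSE),
                         training = train_config()) {
  config$use_attention <- FALSE
  samlp_train(data, config = config, training = training)
}

#' Predict risk labels or probabilities
#'
#' Probabilities come from the deterministic (inference-mode) forward pass;
#' classes threshold them at the config's `classification_threshold`, with
#' ties at the threshold mapped to high risk (label 1) — conservative for a
#' screening tool.
#'
#' @param object A [samlp_train()] fit.
#' @param newdata A feature tibble with the same feature columns the model
#'   was trained on (standardized the same way), or a numeric matrix.
#' @param type `"class"` (default) for 0/1 labels, `"prob"` for
#'   probabilities.
#' @param ... Unused.
#' @return Numeric vector of length `nrow(newdata)`.
#' @export
predict.samlp_fit <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.matrix(newdata)) {
    X <- newdata
  } else {
    fc <- feature_columns(newdata)
    if (!identical(fc, object$feature_names)) {
      stop_value("predict: feature columns differ from the training contract")
    }
    X <- feature_matrix(newdata)
  }
  prob <- as.numeric(samlp_forward(X, object$params, object$config, training = FALSE))
  if (type == "prob") return(prob)
  as.integer(prob >= object$config$classification_threshold)
}

#' @export
print.samlp_fit <- function(x, ...) {
  kind <- if (x$config$use_attention) "SA-MLP" else "DNN baseline"
  cat(sprintf("%s fit: %d train / %d val rows, stopped at epoch %d (best %d)\n",
              kind, x$n_train, x$n_val, x$stopped_epoch, x$best_epoch))
  cat(sprintf("best validation loss: %.5f\n", x$best_val_loss))
  invisible(x)
}

#' Tidy the training history of a fit
#'
#' @param x A `samlp_fit`.
#' @param ... Unused.
#' @return A tibble with one row per trained epoch: `epoch`, `train_loss`,
#'   `val_loss`.
#' @export
tidy.samlp_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x A `samlp_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model kind, epochs run, best epoch, best
#'   validation loss, final training loss, trainable parameter count.
#' @export
glance.samlp_fit <- function(x, ...) {
  tibble::tibble(
    model = if (x$config$use_attention) "sa_mlp" else "dnn",
    epochs_run = x$stopped_epoch,
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    final_train_loss = x$history$train_loss[nrow(x$history)],
    n_parameters = sum(vapply(x$params, length, integer(1)))
  )
}

#' Loss-curve plot for a fit
#'
#' @param object A `samlp_fit`.
#' @param ... Unused.
#' @return A ggplot of training and validation loss per epoch, with the
#'   best epoch marked.
#' @export
autoplot.samlp_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                              names_to = "series", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy",
                  colour = NULL,
                  title = "SA-MLP training history") +
    ggplot2::theme_minimal()
}
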