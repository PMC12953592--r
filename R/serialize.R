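# JSON serialization: human-diffable nested arrays, no binary formats.
# Matrices are written row-major (JSON array of rows) with shapes recorded.

MODEL_LAYOUT_VERSION <- 1L

#' Write a fitted model to JSON
#'
#' The layout is versioned and fully self-describing: architecture and
#' training configs, the feature-name contract, each parameter tensor as a
#' row-major nested array with its shape, and the training history. Numbers
#' are written at full precision so a read-back model predicts identically.
#'
#' @param fit A `samlp_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(fit, path) {
  tensors <- purrr::map(fit$params, function(p) {
    list(shape = if (is.matrix(p)) dim(p) else length(p),
         values = p)
  })
  obj <- list(layout_version = MODEL_LAYOUT_VERSION,
              config = unclass(fit$config),
              training = unclass(fit$training),
              feature_names = fit$feature_names,
              best_epoch = fit$best_epoch,
              stopped_epoch = fit$stopped_epoch,
              best_val_loss = fit$best_val_loss,
              n_train = fit$n_train, n_val = fit$n_val,
              history = fit$history,
              params = tensors)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path A file written by [write_model()].
#' @return A `samlp_fit`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.integer(obj$layout_version), MODEL_LAYOUT_VERSION)) {
    stop_value(sprintf("unsupported model layout version: %s", obj$layout_version))
  }
  params <- purrr::map(obj$params, function(t) {
    v <- t$values
    if (length(t$shape) == 2) {
      m <- if (is.matrix(v)) v else matrix(unlist(v), nrow = t$shape[1], byrow = TRUE)
      storage.mode(m) <- "double"
      stopifnot(all(dim(m) == t$shape))
      m
    } else {
      as.numeric(unlist(v))
    }
  })
  cfg <- do.call(samlp_config, obj$config[setdiff(names(obj$config), character())])
  tr <- do.call(train_config, obj$training)
  structure(list(params = structure(params, class = "samlp_params"),
                 config = cfg, training = tr,
                 history = tibble::as_tibble(obj$history),
                 best_epoch = obj$best_epoch, stopped_epoch = obj$stopped_epoch,
                 best_val_loss = obj$best_val_loss,
                 feature_names = obj$feature_names,
                 n_train = obj$n_train, n_val = obj$n_val),
            class = "samlp_fit")
}

#' Write an evaluation report to JSON
#'
#' Records the raw confusion counts, exact metric fractions and the 2-dp
#' rounded view for each evaluated model. Deterministic content: reruns of
#' the same experiment produce byte-identical files.
#'
#' @param reports Named list; each element a list with `confusion` and
#'   `metrics` as produced by [evaluate_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(reports, path) {
  obj <- purrr::map(reports, function(r) {
    list(confusion = list(tp = r$confusion$tp, fp = r$confusion$fp,
                          tn = r$confusion$tn, fn = r$confusion$fn),
         metrics = r$metrics)
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
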