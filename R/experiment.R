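#' Configuration for a full screening experiment
#'
#' Exactly one of `synth` (a [synth_params()] simulation recipe) or `input`
#' (path to a CSV feature table in the UCI dialect) must be supplied. The
#' global `seed` drives every stochastic stage — simulation, splitting,
#' initialization, shuffling, dropout — through named substreams, so a
#' config replays exactly.
#'
#' @param synth A [synth_params()] object, or `NULL` when reading a file.
#' @param input Path to a feature CSV, or `NULL` when simulating.
#' @param rule A [label_rule()].
#' @param model A [samlp_config()].
#' @param training A [train_config()]; its seed is overridden by the global
#'   seed's training substream.
#' @param test_frac Held-out test fraction (default 0.2).
#' @param seed Global integer seed.
#' @param normalize_before_split If `TRUE`, fit z-score statistics on the
#'   full dataset before splitting (the order some published pipelines use);
#'   default `FALSE` fits on the training partition only, avoiding leakage.
#' @param baselines Character subset of `c("dnn", "knn")` to evaluate
#'   alongside the SA-MLP.
#' @param knn_k Neighbourhood size for the k-NN baseline.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(synth = synth_params(), input = NULL,
                              rule = label_rule(), model = samlp_config(),
                              training = train_config(), test_frac = 0.2,
                              seed = 1L, normalize_before_split = FALSE,
                              baselines = character(), knn_k = 5L) {
  if (is.null(synth) == is.null(input)) {
    stop_config("exactly one of `synth` and `input` must be set")
  }
  if (!all(baselines %in% c("dnn", "knn"))) {
    stop_config("baselines must be a subset of c(\"dnn\", \"knn\")")
  }
  structure(list(synth = synth, input = input, rule = rule, model = model,
                 training = training, test_frac = test_frac,
                 seed = as.integer(seed),
                 normalize_before_split = isTRUE(normalize_before_split),
                 baselines = baselines, knn_k = as.integer(knn_k)),
            class = "experiment_config")
}

#' Run the full screening experiment
#'
#' Executes the pipeline end to end: obtain features (simulate or read),
#' attach rule-based risk labels, stratified 80:20-style split, z-score
#' standardization (training-fitted by default), SA-MLP training with early
#' stopping, optional DNN/k-NN baselines, and confusion-matrix evaluation
#' on the held-out test set. When `out_dir` is given, all artifacts are
#' written there: `labeled.csv`, `split.csv` (row name and partition),
#' `model.json`, `metrics.json` and `report.json`. `metrics.json` content
#' is fully determined by the config, so reruns are byte-identical; the
#' wall-clock note lives only in `report.json`.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory, or `NULL` to skip writing artifacts.
#' @return A list of class `experiment_report`: data provenance, per-class
#'   split sizes, training-history summary, metrics per model and the
#'   parameter audit.
#' @export
#' @examples
#' cfg <- experiment_config(
#'   synth = synth_params(n = 150, seed = 9, target_balance = 0.5),
#'   training = train_config(epochs = 3), seed = 9
#' )
#' rep <- run_experiment(cfg)
#' rep$metrics$sa_mlp$metrics
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)), parent = e)
    })
  }

  # data: simulate or read, then label with the rule
  data_seed <- substream_seed(config$seed, "data")
  if (!is.null(config$synth)) {
    sp <- config$synth
    sp$seed <- data_seed
    labelled <- stage("simulate", simulate_labeled_dataset(sp, config$rule))
    provenance <- list(source = "synthetic", seed = data_seed,
                       n = sp$n, target_balance = sp$target_balance)
  } else {
    tbl <- stage("read", read_feature_table(config$input))
    labelled <- stage("label", assign_labels(tbl, config$rule))
    provenance <- list(source = config$input,
                       sha = unname(tools::md5sum(config$input)))
  }
  inform(sprintf("[data] %d rows, %d high risk (seed substream %d)",
                 nrow(labelled), sum(labelled$risk_label), data_seed))

  split_seed <- substream_seed(config$seed, "split")
  if (config$normalize_before_split) {
    stats <- stage("normalize", zscore_fit(labelled))
    labelled_std <- zscore_apply(labelled, stats)
    parts <- stage("split", stratified_split(labelled_std, config$test_frac, split_seed))
    train_std <- parts$train; test_std <- parts$test
  } else {
    parts <- stage("split", stratified_split(labelled, config$test_frac, split_seed))
    stats <- stage("normalize", zscore_fit(parts$train))
    train_std <- zscore_apply(parts$train, stats)
    test_std <- zscore_apply(parts$test, stats)
  }
  split_sizes <- dplyr::count(
    dplyr::bind_rows(train = parts$train, test = parts$test, .id = "partition"),
    .data$partition, .data$risk_label)
  inform(sprintf("[split] train %d / test %d (seed substream %d)",
                 nrow(train_std), nrow(test_std), split_seed))

  tr <- config$training
  tr$seed <- substream_seed(config$seed, "train")
  fit <- stage("train", samlp_train(train_std, config$model, tr))
  inform(sprintf("[train] stopped epoch %d, best epoch %d (seed substream %d)",
                 fit$stopped_epoch, fit$best_epoch, tr$seed))

  metrics <- list(sa_mlp = stage("evaluate", evaluate_model(fit, test_std)))
  fits <- list(sa_mlp = fit)
  if ("dnn" %in% config$baselines) {
    trd <- tr
    trd$seed <- substream_seed(config$seed, "train-dnn")
    fits$dnn <- stage("train-dnn", dnn_baseline(train_std, training = trd))
    metrics$dnn <- evaluate_model(fits$dnn, test_std)
  }
  if ("knn" %in% config$baselines) {
    pred <- stage("knn", knn_predict(train_std, test_std, k = config$knn_k))
    cm <- confusion_matrix(test_std$risk_label, pred)
    metrics$knn <- list(confusion = cm, metrics = screening_metrics(cm))
  }

  report <- structure(list(
    provenance = provenance,
    seed = config$seed,
    split_sizes = split_sizes,
    normalization = list(fitted_on = if (config$normalize_before_split) "all" else "train",
                         ddof = attr(stats, "ddof")),
    history = purrr::map(fits, glance),
    metrics = metrics,
    param_audit = param_audit(config$model),
    wall_clock_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "experiment_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(labelled, file.path(out_dir, "labeled.csv"))
    readr::write_csv(dplyr::bind_rows(
      tibble::tibble(name = parts$train$name, partition = "train"),
      tibble::tibble(name = parts$test$name, partition = "test")
    ), file.path(out_dir, "split.csv"), progress = FALSE)
    write_model(fit, file.path(out_dir, "model.json"))
    write_metrics_json(metrics, file.path(out_dir, "metrics.json"))
    rep_json <- list(provenance = provenance, seed = config$seed,
                     split_sizes = split_sizes,
                     history = purrr::map(report$history, as.list),
                     wall_clock_s = report$wall_clock_s)
    jsonlite::write_json(rep_json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("screening experiment\n")
  cat(sprintf("  data: %s\n", x$provenance$source))
  cat("  split sizes:\n")
  print(x$split_sizes)
  for (nm in names(x$metrics)) {
    cat(sprintf("  %s metrics (rounded):\n", nm))
    m <- x$metrics[[nm]]$metrics
    cat("   ", paste(sprintf("%s=%.2f", m$metric, m$rounded), collapse = " "), "\n")
  }
  invisible(x)
}

#' Read an experiment configuration from YAML or JSON
#'
#' The file mirrors the [experiment_config()] arguments: top-level keys
#' `synth`, `input`, `rule`, `model`, `training`, `test_frac`, `seed`,
#' `normalize_before_split`, `baselines`, `knn_k`; each structured key holds
#' the corresponding constructor's arguments.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  # YAML 1.1 reads a bare `n` key as boolean FALSE; restore it
  if (!is.null(raw$synth)) {
    names(raw$synth)[names(raw$synth) == "FALSE"] <- "n"
  }
  args <- list(
    synth = if (!is.null(raw$synth)) do.call(synth_params, raw$synth) else NULL,
    input = raw$input,
    rule = if (!is.null(raw$rule)) do.call(label_rule, raw$rule) else label_rule(),
    model = if (!is.null(raw$model)) do.call(samlp_config, raw$model) else samlp_config(),
    training = if (!is.null(raw$training)) do.call(train_config, raw$training) else train_config(),
    test_frac = raw$test_frac %||% 0.2,
    seed = raw$seed %||% 1L,
    normalize_before_split = raw$normalize_before_split %||% FALSE,
    baselines = raw$baselines %||% character(),
    knn_k = raw$knn_k %||% 5L
  )
  do.call(experiment_config, args)
}
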