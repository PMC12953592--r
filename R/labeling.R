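#' The HNR/jitter risk-labelling rule
#'
#' A recording is labelled low depression risk (0) only when voice quality is
#' good on both axes: HNR strictly above `hnr_min` (harmonic-rich, non-breathy
#' phonation) and jitter strictly below `jitter_max` (stable pitch). Every
#' other combination — including equality with either threshold — is high
#' risk (1). The rule is a heuristic screening proxy, not a clinical
#' diagnostic boundary.
#'
#' @param hnr_min HNR threshold in dB (default 20); low risk requires
#'   HNR > `hnr_min` strictly.
#' @param jitter_max Jitter threshold as a raw fraction (default 0.005); low
#'   risk requires jitter < `jitter_max` strictly.
#' @return An object of class `label_rule`.
#' @export
#' @examples
#' rule <- label_rule()
#' assign_label(25, 0.003, rule) # 0: low risk
#' assign_label(20, 0.003, rule) # 1: boundary is high risk
label_rule <- function(hnr_min = 20, jitter_max = 0.005) {
  if (!is.finite(hnr_min)) stop_config("hnr_min must be finite")
  if (!is.finite(jitter_max) || jitter_max <= 0) stop_config("jitter_max must be > 0")
  structure(list(hnr_min = hnr_min, jitter_max = jitter_max), class = "label_rule")
}

#' @export
print.label_rule <- function(x, ...) {
  cat(sprintf("risk rule: low risk iff HNR > %g dB and jitter < %g (strict)\n",
              x$hnr_min, x$jitter_max))
  invisible(x)
}

#' Heaviside step function
#'
#' `H(x) = 1` for `x > 0` strictly, else 0 — in particular `H(0) = 0`. This
#' is the algebraic primitive behind the labelling rule; its zero-at-zero
#' convention is what makes threshold-equality cases high risk.
#'
#' @param x Numeric vector; must be free of NaN/NA.
#' @return Integer vector of 0/1.
#' @export
heaviside <- function(x) {
  if (any(is.na(x))) stop_value("heaviside: NaN/NA input")
  as.integer(x > 0)
}

#' Assign a risk label to raw HNR/jitter values
#'
#' Computed via the Heaviside product form
#' `y = 1 - H(hnr - hnr_min) * H(jitter_max - jitter)`, which is identical to
#' the conjunction form "0 iff hnr > hnr_min and jitter < jitter_max" on all
#' inputs including the threshold boundaries (where `H(0) = 0` forces label
#' 1). Operates on raw, unnormalized values: the thresholds are in raw units
#' (dB, fraction).
#'
#' @param hnr,jitter Numeric vectors (recycled to common length).
#' @param rule A [label_rule()].
#' @return Integer vector of labels in \{0, 1\}; 1 = high risk.
#' @export
assign_label <- function(hnr, jitter, rule = label_rule()) {
  if (any(is.na(hnr)) || any(is.na(jitter))) stop_value("assign_label: NaN/NA input")
  1L - heaviside(hnr - rule$hnr_min) * heaviside(rule$jitter_max - jitter)
}

#' Conjunction form of the risk rule
#'
#' The direct if/else statement of the rule: label 0 iff `hnr > hnr_min`
#' and `jitter < jitter_max`, both strict; 1 otherwise. Exported so the
#' algebraic (Heaviside) route in [assign_label()] can be property-checked
#' against it; the two agree everywhere.
#'
#' @inheritParams assign_label
#' @return Integer vector of labels in \{0, 1\}.
#' @export
assign_label_conjunction <- function(hnr, jitter, rule = label_rule()) {
  if (any(is.na(hnr)) || any(is.na(jitter))) stop_value("assign_label: NaN/NA input")
  ifelse(hnr > rule$hnr_min & jitter < rule$jitter_max, 0L, 1L)
}

#' Attach simulated risk labels to a feature table
#'
#' Applies [assign_label()] row-wise to the table's HNR and jitter columns
#' and appends the result as an integer `risk_label` column. The feature
#' columns are unchanged; the label depends only on the two rule columns.
#'
#' @param data A feature tibble.
#' @param rule A [label_rule()].
#' @param aliases Alias map locating the rule columns.
#' @return The tibble with a `risk_label` column (1 = high risk).
#' @export
assign_labels <- function(data, rule = label_rule(), aliases = default_aliases()) {
  hnr_col <- resolve_column(data, "hnr", aliases)
  jit_col <- resolve_column(data, "jitter", aliases)
  if (is.na(hnr_col) || is.na(jit_col)) {
    stop_schema("cannot locate HNR and/or jitter columns for labelling")
  }
  dplyr::mutate(data, risk_label = assign_label(.data[[hnr_col]], .data[[jit_col]], rule))
}

#' Fit per-feature z-score normalization statistics
#'
#' Computes the mean and standard deviation of every feature column. The
#' population convention (divide by n) is the default; set `ddof = 1` for
#' the sample convention. A constant column is a degenerate feature (zero
#' sigma would make the transform undefined) and raises an error naming it.
#'
#' @param data A feature tibble with n >= 2 rows.
#' @param ddof Delta degrees of freedom: 0 (population, default) or 1.
#' @return A tibble of class `zscore_stats` with columns `feature`, `mu`,
#'   `sigma`; the `ddof` convention is stored as an attribute.
#' @export
#' @examples
#' tbl <- tibble::tibble(name = c("a", "b", "c"), HNR = c(1, 2, 3),
#'                       `MDVP:Jitter(%)` = c(0.1, 0.2, 0.3))
#' zscore_fit(tbl)
zscore_fit <- function(data, ddof = 0) {
  if (nrow(data) < 2) stop_value("zscore_fit: need at least 2 rows")
  if (!ddof %in% c(0, 1)) stop_config("ddof must be 0 or 1")
  fc <- feature_columns(data)
  n <- nrow(data)
  stats <- purrr::map_dfr(fc, function(fn) {
    v <- data[[fn]]
    mu <- mean(v)
    sigma <- sqrt(sum((v - mu)^2) / (n - ddof))
    tibble::tibble(feature = fn, mu = mu, sigma = sigma)
  })
  degenerate <- stats$feature[stats$sigma == 0]
  if (length(degenerate) > 0) {
    stop_value(sprintf("degenerate feature (zero standard deviation): %s",
                       paste(degenerate, collapse = ", ")))
  }
  structure(stats, class = c("zscore_stats", class(stats)), ddof = ddof)
}

#' Apply fitted z-score statistics to a table
#'
#' Transforms each feature column as `(x - mu) / sigma` using statistics
#' fitted elsewhere (typically on the training partition; no refitting
#' happens here). The table's feature names must match the fit exactly.
#'
#' @param data A feature tibble.
#' @param stats A [zscore_fit()] result.
#' @return The tibble with standardized feature columns.
#' @export
zscore_apply <- function(data, stats) {
  fc <- feature_columns(data)
  if (!setequal(fc, stats$feature)) {
    stop_value("zscore_apply: feature names do not match the fitted statistics")
  }
  for (i in seq_len(nrow(stats))) {
    fn <- stats$feature[[i]]
    data[[fn]] <- (data[[fn]] - stats$mu[[i]]) / stats$sigma[[i]]
  }
  data
}

#' Stratified train/test split
#'
#' Partitions a labelled dataset so that each class contributes
#' `round(class_count * test_frac)` test rows (half-up), with a largest-
#' remainder adjustment of at most one row per class so the total test size
#' equals `round(n * test_frac)` exactly. Selection within a class is
#' uniform under the seed; train and test are disjoint and exhaustive.
#'
#' @param data A tibble with a binary `risk_label` column, both classes
#'   present.
#' @param test_frac Test fraction in (0, 1); default 0.2.
#' @param seed Integer seed for the within-class selection.
#' @return A list with tibbles `train` and `test`.
#' @export
stratified_split <- function(data, test_frac = 0.2, seed = 1L) {
  if (!"risk_label" %in% names(data)) stop_value("stratified_split: no risk_label column")
  if (test_frac <= 0 || test_frac >= 1) stop_config("test_frac must be in (0, 1)")
  y <- data$risk_label
  classes <- sort(unique(y))
  counts <- vapply(classes, function(cl) sum(y == cl), integer(1))
  if (length(classes) < 2) {
    abort("stratified_split: need both classes present",
          class = "voicerisk_stratification_error")
  }
  n <- nrow(data)
  half_up <- function(x) floor(x + 0.5)
  target_total <- half_up(n * test_frac)
  raw <- counts * test_frac
  take <- half_up(raw)
  # largest-remainder adjustment so per-class takes sum to the total
  delta <- target_total - sum(take)
  if (delta != 0) {
    frac <- raw - floor(raw)
    ord <- order(if (delta > 0) -frac else frac)
    for (i in seq_len(abs(delta))) {
      j <- ord[((i - 1) %% length(classes)) + 1]
      take[j] <- take[j] + sign(delta)
    }
  }
  take <- pmin(pmax(take, 0L), counts)
  set.seed(seed)
  test_idx <- integer(0)
  for (k in seq_along(classes)) {
    idx <- which(y == classes[k])
    test_idx <- c(test_idx, idx[sample.int(length(idx), take[k])])
  }
  list(train = data[-test_idx, , drop = FALSE],
       test  = data[sort(test_idx), , drop = FALSE])
}
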