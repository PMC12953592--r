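#' Read a voice-feature table in the UCI Parkinson's CSV dialect
#'
#' Reads a comma-separated file with a header row whose first column, `name`,
#' identifies the subject/recording. A `status` column (the UCI Parkinson's
#' diagnosis flag), if present, is dropped with a notice: risk labels in this
#' package are simulated from the acoustic features, not taken from the PD
#' diagnosis. The remaining columns become numeric features in file order.
#'
#' @param path Path to a CSV file.
#' @param strict If `TRUE` (default) require exactly the 22 canonical feature
#'   columns; if `FALSE`, accept any d >= 2 feature columns provided the HNR
#'   and jitter columns are locatable via `aliases`.
#' @param aliases Alias map for the rule-defining columns, see
#'   [default_aliases()].
#' @return A tibble with a character `name` column followed by numeric
#'   feature columns.
#' @export
#' @examples
#' tbl <- simulate_voice_features(synth_params(n = 5, seed = 1))
#' f <- tempfile(fileext = ".csv")
#' write_feature_table(tbl, f)
#' read_feature_table(f)
read_feature_table <- function(path, strict = TRUE, aliases = default_aliases()) {
  if (!file.exists(path)) {
    stop_parse(sprintf("file not found: %s", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) stop_schema("empty table: no data rows under the header")
  if (!"name" %in% names(raw)) {
    stop_schema("missing header: expected a `name` column identifying each recording")
  }
  if ("status" %in% names(raw)) {
    inform("dropping `status` column: risk labels are simulated, not the PD diagnosis")
    raw$status <- NULL
  }
  feat_names <- setdiff(names(raw), "name")
  out <- tibble::tibble(name = as.character(raw$name))
  for (fn in feat_names) {
    v <- suppressWarnings(as.numeric(raw[[fn]]))
    bad <- which(is.na(v) & !is.na(raw[[fn]]) & raw[[fn]] != "NA")
    if (length(bad) > 0) {
      stop_parse(sprintf("non-numeric cell at row %d, column `%s`: %s",
                         bad[[1]], fn, raw[[fn]][bad[[1]]]))
    }
    out[[fn]] <- v
  }
  if ("risk_label" %in% names(out)) out$risk_label <- as.integer(out$risk_label)
  check_rule_columns(out, strict = strict, aliases = aliases,
                     d = length(setdiff(feat_names, "risk_label")))
  out
}

check_rule_columns <- function(data, strict, aliases, d) {
  if (strict && d != 22L) {
    stop_schema(sprintf("expected 22 feature columns in strict mode, found %d", d))
  }
  if (!strict && d < 2L) {
    stop_schema(sprintf("need at least 2 feature columns, found %d", d))
  }
  for (key in c("hnr", "jitter")) {
    if (is.na(resolve_column(data, key, aliases))) {
      stop_schema(sprintf("missing rule column: none of [%s] present",
                          paste(aliases[[key]], collapse = ", ")))
    }
  }
  invisible(data)
}

#' Write a voice-feature table as CSV
#'
#' Writes the UCI dialect back out: header row, `name` first, features in
#' stored column order, full round-trippable numeric precision (at least 6
#' significant digits). `write_feature_table()` then [read_feature_table()]
#' is the identity on the table.
#'
#' @param data A feature tibble (as returned by [read_feature_table()] or
#'   [simulate_voice_features()]); a `risk_label` column, if present, is
#'   written too so labelled datasets round-trip.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path) {
  if (!"name" %in% names(data)) {
    stop_schema("table has no `name` column")
  }
  data <- dplyr::relocate(data, "name")
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Validate a feature table against the pipeline's schema requirements
#'
#' A reporting operation: it never raises. Checks that the rule-defining
#' columns (HNR, jitter) are locatable, that every feature cell is finite,
#' that there is at least one row, and that subject names are unique.
#' When `ok` is `TRUE` the labelling/training pipeline cannot fail on
#' schema grounds.
#'
#' @param data A feature tibble.
#' @param aliases Alias map for the rule columns.
#' @return An object of class `voicerisk_validation`: a list with `ok`
#'   (logical) and `messages` (character vector of problems, empty when ok).
#' @export
validate_schema <- function(data, aliases = default_aliases()) {
  msgs <- character()
  if (!"name" %in% names(data)) msgs <- c(msgs, "missing `name` column")
  if (nrow(data) < 1) msgs <- c(msgs, "table has no rows")
  for (key in c("hnr", "jitter")) {
    if (is.na(resolve_column(data, key, aliases))) {
      msgs <- c(msgs, sprintf("missing rule column (aliases tried: %s)",
                              paste(aliases[[key]], collapse = ", ")))
    }
  }
  for (fn in feature_columns(data)) {
    v <- data[[fn]]
    if (!is.numeric(v)) {
      msgs <- c(msgs, sprintf("column `%s` is not numeric", fn))
      next
    }
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      msgs <- c(msgs, sprintf("non-finite value at row %d, column `%s`", bad[[1]], fn))
    }
  }
  if ("name" %in% names(data)) {
    dup <- unique(data$name[duplicated(data$name)])
    if (length(dup) > 0) {
      msgs <- c(msgs, sprintf("duplicate subject names: %s",
                              paste(head(dup, 3), collapse = ", ")))
    }
  }
  structure(list(ok = length(msgs) == 0, messages = msgs),
            class = "voicerisk_validation")
}

#' @export
print.voicerisk_validation <- function(x, ...) {
  if (x$ok) {
    cat("schema validation: ok\n")
  } else {
    cat("schema validation: FAILED\n")
    for (m in x$messages) cat(" -", m, "\n")
  }
  invisible(x)
}

# Feature matrix view of a tibble: rows = samples, named columns = features.
feature_matrix <- function(data) {
  fc <- feature_columns(data)
  m <- as.matrix(dplyr::select(data, dplyr::all_of(fc)))
  storage.mode(m) <- "double"
  rownames(m) <- NULL
  m
}
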