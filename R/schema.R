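#' Canonical UCI Parkinson's voice-feature schema
#'
#' The UCI Parkinson's voice table (`parkinsons.data`) carries one `name`
#' column identifying the recording, 22 numeric acoustic features extracted by
#' MDVP-style analysis of sustained phonation, and a `status` diagnosis flag.
#' `uci_feature_names()` returns the 22 feature column names in file order.
#'
#' Two of the columns drive the risk-labelling rule: `HNR` (harmonics-to-noise
#' ratio, dB) and `MDVP:Jitter(%)` (cycle-to-cycle fundamental-frequency
#' variation, stored as a raw fraction, e.g. 0.005).
#'
#' @return Character vector of length 22.
#' @export
#' @examples
#' uci_feature_names()
uci_feature_names <- function() {
  c(
    "MDVP:Fo(Hz)", "MDVP:Fhi(Hz)", "MDVP:Flo(Hz)",
    "MDVP:Jitter(%)", "MDVP:Jitter(Abs)", "MDVP:RAP", "MDVP:PPQ",
    "Jitter:DDP",
    "MDVP:Shimmer", "MDVP:Shimmer(dB)", "Shimmer:APQ3", "Shimmer:APQ5",
    "MDVP:APQ", "Shimmer:DDA",
    "NHR", "HNR",
    "RPDE", "DFA",
    "spread1", "spread2", "D2", "PPE"
  )
}

#' Default alias map for the rule-defining columns
#'
#' Column identification is by exact header name, with a configurable alias
#' map because informal spellings of the two rule features are common
#' ("HNR", "Jitter (%)"). Each element is a character vector of acceptable
#' header names, first match wins.
#'
#' @return Named list with elements `hnr` and `jitter`.
#' @export
default_aliases <- function() {
  list(
    hnr    = c("HNR", "hnr"),
    jitter = c("MDVP:Jitter(%)", "Jitter(%)", "Jitter (%)", "jitter_pct")
  )
}

# Resolve the actual column name for a rule feature; NA if absent.
resolve_column <- function(data, key, aliases = default_aliases()) {
  hit <- intersect(aliases[[key]], names(data))
  if (length(hit) == 0) NA_character_ else hit[[1]]
}

# Non-feature bookkeeping columns that may ride along in a tibble.
reserved_columns <- function() c("name", "status", "risk_label")

# Names of the numeric feature columns of a table (everything that is not
# bookkeeping).
feature_columns <- function(data) {
  setdiff(names(data), reserved_columns())
}

stop_schema <- function(msg) abort(msg, class = "voicerisk_schema_error")
stop_parse  <- function(msg) abort(msg, class = "voicerisk_parse_error")
stop_value  <- function(msg) abort(msg, class = "voicerisk_value_error")
stop_config <- function(msg) abort(msg, class = "voicerisk_config_error")
stop_shape  <- function(msg) abort(msg, class = "voicerisk_shape_error")
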