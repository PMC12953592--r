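#' Parameters for the synthetic voice-feature generator
#'
#' The generator emulates the UCI Parkinson's table schema so the whole
#' pipeline runs without any download. HNR is drawn from a normal truncated
#' to the physiologically plausible 8--35 dB band; jitter is log-normal
#' (right-skewed, strictly positive, median at the rule threshold 0.005 by
#' default so the decision boundary crosses the bulk of the data); the two
#' are coupled through a Gaussian copula with correlation `rho` between HNR
#' and -log(jitter) — better voices have higher HNR and lower jitter. The
#' remaining 20 canonical features are independent standard-normal
#' placeholders carrying no label signal.
#'
#' @param n Number of recordings to simulate.
#' @param seed Integer master seed; all randomness derives from it via named
#'   substreams.
#' @param hnr_mean,hnr_sd Pre-truncation HNR mean / sd in dB.
#' @param jitter_log_mean,jitter_log_sd Mean / sd of log(jitter); defaults
#'   put the jitter median at 0.005 with a realistic skewed spread.
#' @param rho Copula correlation in \[-1, 1\] between HNR and -log(jitter).
#' @param target_balance `"natural"` (labels as the rule produces them) or a
#'   fraction in (0, 1): the desired share of high-risk (label 1) samples,
#'   achieved exactly by per-class rejection sampling in
#'   [simulate_labeled_dataset()].
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(n = 200L, seed = 1L,
                         hnr_mean = 22, hnr_sd = 4.5,
                         jitter_log_mean = log(0.005), jitter_log_sd = 0.45,
                         rho = 0.5, target_balance = "natural") {
  if (n < 1) stop_config("n must be a positive count")
  if (hnr_sd <= 0 || jitter_log_sd <= 0) stop_config("sd parameters must be > 0")
  if (abs(rho) > 1) stop_config("|rho| must be <= 1")
  if (is.numeric(target_balance) &&
      (target_balance <= 0 || target_balance >= 1)) {
    stop_config("target_balance must be in (0, 1) or \"natural\"")
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 hnr_mean = hnr_mean, hnr_sd = hnr_sd,
                 jitter_log_mean = jitter_log_mean, jitter_log_sd = jitter_log_sd,
                 rho = rho, target_balance = target_balance),
            class = "synth_params")
}

# Derive a reproducible 32-bit sub-seed from a master seed and a stream
# label, so adding a stream never perturbs another.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1000003 + h * 7919) %% 2147483647)
}

# Inverse-CDF truncated normal on [lo, hi] from standard-normal draws z.
truncnorm_from_z <- function(z, mean, sd, lo, hi) {
  plo <- pnorm((lo - mean) / sd)
  phi <- pnorm((hi - mean) / sd)
  qnorm(plo + pnorm(z) * (phi - plo)) * sd + mean
}

#' Simulate a schema-conformant voice-feature table
#'
#' Deterministic given the seed in `params`: the same parameters always yield
#' a bit-identical table. See [synth_params()] for the generative model.
#'
#' @param params A [synth_params()] object.
#' @return A feature tibble with `name` plus the 22 canonical columns,
#'   passing [validate_schema()].
#' @export
#' @examples
#' tbl <- simulate_voice_features(synth_params(n = 10, seed = 42))
#' validate_schema(tbl)$ok
simulate_voice_features <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  n <- params$n
  set.seed(substream_seed(params$seed, "rule-features"))
  e1 <- rnorm(n)
  e2 <- rnorm(n)
  z_hnr <- e1
  z_jit <- params$rho * e1 + sqrt(1 - params$rho^2) * e2
  hnr <- truncnorm_from_z(z_hnr, params$hnr_mean, params$hnr_sd, 8, 35)
  jitter <- exp(params$jitter_log_mean - params$jitter_log_sd * z_jit)

  others <- setdiff(uci_feature_names(), c("HNR", "MDVP:Jitter(%)"))
  set.seed(substream_seed(params$seed, "placeholder-features"))
  placeholder <- matrix(rnorm(n * length(others)), nrow = n,
                        dimnames = list(NULL, others))

  out <- tibble::as_tibble(placeholder)
  out$HNR <- hnr
  out[["MDVP:Jitter(%)"]] <- jitter
  out <- dplyr::select(out, dplyr::all_of(uci_feature_names()))
  dplyr::bind_cols(tibble::tibble(name = sprintf("synth_%d", seq_len(n))), out)
}

#' Simulate a labelled dataset, optionally at an exact class balance
#'
#' Labels always come from [assign_labels()] applied to generated features —
#' never assigned independently of the rule. With `target_balance =
#' "natural"` the class mix is whatever the rule produces; with a fraction,
#' per-class rejection sampling draws batches until the requested counts
#' (high-risk share rounded half-up) are met exactly, then shuffles row
#' order under a substream of the seed.
#'
#' @param params A [synth_params()] object.
#' @param rule A [label_rule()].
#' @param max_batches Rejection-sampling cap; degenerate parameters that
#'   cannot reach the requested balance error out after this many batches.
#' @return A tibble with the 22 features and a `risk_label` column.
#' @export
simulate_labeled_dataset <- function(params, rule = label_rule(), max_batches = 200L) {
  stopifnot(inherits(params, "synth_params"))
  if (identical(params$target_balance, "natural")) {
    return(assign_labels(simulate_voice_features(params), rule))
  }
  n <- params$n
  n1 <- as.integer(floor(n * params$target_balance + 0.5))
  n0 <- n - n1
  got <- list(`0` = NULL, `1` = NULL)
  need <- c(`0` = n0, `1` = n1)
  for (batch in seq_len(max_batches)) {
    bp <- params
    bp$seed <- substream_seed(params$seed, sprintf("balance-batch-%d", batch))
    bp$n <- n
    labelled <- assign_labels(simulate_voice_features(bp), rule)
    for (cl in c("0", "1")) {
      have <- if (is.null(got[[cl]])) 0L else nrow(got[[cl]])
      if (have < need[[cl]]) {
        pool <- dplyr::filter(labelled, .data$risk_label == as.integer(cl))
        got[[cl]] <- dplyr::bind_rows(got[[cl]],
                                      head(pool, need[[cl]] - have))
      }
    }
    done <- all(vapply(c("0", "1"), function(cl) {
      (if (is.null(got[[cl]])) 0L else nrow(got[[cl]])) >= need[[cl]]
    }, logical(1)))
    if (done) {
      out <- dplyr::bind_rows(got[["0"]], got[["1"]])
      set.seed(substream_seed(params$seed, "balance-shuffle"))
      out <- out[sample.int(nrow(out)), , drop = FALSE]
      out$name <- sprintf("synth_%d", seq_len(nrow(out)))
      return(out)
    }
  }
  abort(sprintf("could not reach target balance %.3f within %d batches",
                params$target_balance, max_batches),
        class = "voicerisk_sampling_error")
}

#' Fixed boundary fixtures for the labelling rule
#'
#' A deterministic 9-row table covering the full 3x3 grid of HNR in
#' \{15, 20, 25\} dB by jitter in \{0.003, 0.005, 0.007\}: all four threshold
#' quadrants plus the exact-boundary rows (HNR = 20 exactly, jitter = 0.005
#' exactly). Labels are attached through [assign_labels()]; only the
#' (25, 0.003) cell — strictly inside the good-voice region — is low risk.
#' All non-rule features are zero.
#'
#' @param rule A [label_rule()]; the grid targets the default thresholds.
#' @return A labelled tibble with 9 rows.
#' @export
boundary_fixture_dataset <- function(rule = label_rule()) {
  grid <- tidyr::expand_grid(hnr = c(15, 20, 25), jitter = c(0.003, 0.005, 0.007))
  out <- tibble::tibble(name = sprintf("boundary_%d", seq_len(nrow(grid))))
  for (fn in uci_feature_names()) {
    out[[fn]] <- if (fn == "HNR") grid$hnr
                 else if (fn == "MDVP:Jitter(%)") grid$jitter
                 else 0
  }
  assign_labels(out, rule)
}
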