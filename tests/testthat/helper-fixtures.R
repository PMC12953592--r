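# In-code fixtures: no files on disk, everything is built at test time.

fmat <- function(d) voicerisk:::feature_matrix(d)

# A minimal hand-written table in the canonical 22-column schema.
tiny_table <- function(n = 3) {
  out <- tibble::tibble(name = sprintf("subj_%d", seq_len(n)))
  for (fn in uci_feature_names()) {
    out[[fn]] <- seq_len(n) + which(uci_feature_names() == fn) / 10
  }
  out$HNR <- c(25, 18, 22)[seq_len(n)]
  out[["MDVP:Jitter(%)"]] <- c(0.003, 0.007, 0.0049)[seq_len(n)]
  out
}

# The tiny model configuration used for gradient checks.
tiny_config <- function(dropout = 0) {
  samlp_config(input_dim = 3L, hidden_dim = 4L, num_heads = 2L, key_dim = 2L,
               dense2_dim = 2L, dropout_rate = dropout)
}

# A small standardized labelled dataset for training tests.
small_training_set <- function(n = 200, seed = 7, balance = 0.5) {
  ds <- simulate_labeled_dataset(synth_params(n = n, seed = seed,
                                              target_balance = balance))
  zscore_apply(ds, zscore_fit(ds))
}
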