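#' Architecture configuration of the SA-MLP classifier
#'
#' The network is: input (22 features) -> dense 64 (ReLU) -> multi-head
#' self-attention over the hidden vector (4 heads, key dimension 16, so the
#' 64 channels split exactly across heads) -> residual add + layer
#' normalization -> dense 32 (ReLU) -> dropout -> sigmoid output neuron.
#' Each sample's hidden vector is treated as a single attention token; see
#' the methods vignette for why the per-layer output sizes force that
#' convention.
#'
#' @param input_dim Number of input features (default 22, the UCI schema).
#' @param hidden_dim First dense layer width (default 64).
#' @param num_heads Attention heads (default 4).
#' @param key_dim Per-head channel count (default 16); `num_heads * key_dim`
#'   must equal `hidden_dim`.
#' @param dense2_dim Second dense layer width (default 32).
#' @param dropout_rate Dropout probability after the second dense layer
#'   (default 0.2), active only during training.
#' @param layernorm_eps Variance guard in layer normalization (default 1e-3).
#' @param classification_threshold Probability cut for [predict.samlp_fit()]
#'   (default 0.5); ties at the threshold map to high risk.
#' @param use_attention `FALSE` replaces the attention block by the identity
#'   (the plain-DNN baseline): the first dense output feeds layer
#'   normalization directly and the Q/K/V/O projections are dropped.
#' @return A list of class `samlp_config`.
#' @export
samlp_config <- function(input_dim = 22L, hidden_dim = 64L, num_heads = 4L,
                         key_dim = 16L, dense2_dim = 32L, dropout_rate = 0.2,
                         layernorm_eps = 1e-3, classification_threshold = 0.5,
                         use_attention = TRUE) {
  dims <- c(input_dim, hidden_dim, num_heads, key_dim, dense2_dim)
  if (any(dims < 1)) stop_config("all dimensions must be positive")
  if (use_attention && num_heads * key_dim != hidden_dim) {
    stop_config(sprintf("num_heads * key_dim (%d) must equal hidden_dim (%d)",
                        num_heads * key_dim, hidden_dim))
  }
  if (dropout_rate < 0 || dropout_rate >= 1) stop_config("dropout_rate must be in [0, 1)")
  if (layernorm_eps <= 0) stop_config("layernorm_eps must be > 0")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dim = as.integer(hidden_dim),
                 num_heads = as.integer(num_heads),
                 key_dim = as.integer(key_dim),
                 dense2_dim = as.integer(dense2_dim),
                 dropout_rate = dropout_rate,
                 layernorm_eps = layernorm_eps,
                 classification_threshold = classification_threshold,
                 use_attention = isTRUE(use_attention)),
            class = "samlp_config")
}

#' Training configuration for the SA-MLP
#'
#' Mini-batch Adam on binary cross-entropy with seeded per-epoch shuffling
#' and early stopping on a validation carve-out: training stops after
#' `patience` epochs without a validation-loss improvement and the
#' best-epoch weights are restored. `patience <= 0` or
#' `patience >= epochs` effectively disables early stopping (all epochs
#' run).
#'
#' @param learning_rate Adam step size (default 0.001).
#' @param batch_size Mini-batch size (default 16).
#' @param epochs Maximum epochs (default 50).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param val_frac Fraction of the training data carved out (stratified) as
#'   the early-stopping validation set (default 0.1); 0 monitors training
#'   loss instead.
#' @param seed Integer seed driving initialization, the validation
#'   carve-out, shuffling and dropout.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment constants
#'   (0.9 / 0.999 / 1e-8).
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 16L, epochs = 50L,
                         patience = 10L, val_frac = 0.1, seed = 1L,
                         adam_beta1 = 0.9, adam_beta2 = 0.999, adam_eps = 1e-8) {
  if (learning_rate <= 0) stop_config("learning_rate must be > 0")
  if (batch_size < 1 || epochs < 1) stop_config("batch_size and epochs must be >= 1")
  if (val_frac < 0 || val_frac >= 0.5) stop_config("val_frac must be in [0, 0.5)")
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 val_frac = val_frac, seed = as.integer(seed),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps),
            class = "train_config")
}
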