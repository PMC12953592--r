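# Forward-pass primitives of the SA-MLP. Row convention throughout: samples
# are rows, so a dense layer is X %*% W + b with W of shape in x out.

glorot_uniform <- function(fan_in, fan_out) {
  bound <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -bound, bound), nrow = fan_in)
}

#' Initialize SA-MLP parameters
#'
#' Dense and projection kernels are Glorot-uniform (bound
#' `sqrt(6/(fan_in+fan_out))`), all biases zero, layer-norm scale `gamma = 1`
#' and shift `beta = 0`. Deterministic per seed.
#'
#' @param config A [samlp_config()].
#' @param seed Integer seed.
#' @return A named list of parameter tensors (class `samlp_params`):
#'   `W1,b1` (input dense), `WQ,bQ,WK,bK,WV,bV` (query/key/value
#'   projections), `WO,bO` (attention output projection), `gamma,beta`
#'   (layer norm), `W2,b2` (second dense), `W3,b3` (output head). The
#'   attention tensors are absent when `use_attention = FALSE`.
#' @export
init_params <- function(config, seed = 1L) {
  set.seed(seed)
  H <- config$hidden_dim
  p <- list(
    W1 = glorot_uniform(config$input_dim, H),
    b1 = numeric(H)
  )
  if (config$use_attention) {
    p$WQ <- glorot_uniform(H, H); p$bQ <- numeric(H)
    p$WK <- glorot_uniform(H, H); p$bK <- numeric(H)
    p$WV <- glorot_uniform(H, H); p$bV <- numeric(H)
    p$WO <- glorot_uniform(H, H); p$bO <- numeric(H)
  }
  p$gamma <- rep(1, H)
  p$beta <- numeric(H)
  p$W2 <- glorot_uniform(H, config$dense2_dim); p$b2 <- numeric(config$dense2_dim)
  p$W3 <- glorot_uniform(config$dense2_dim, 1L); p$b3 <- numeric(1)
  structure(p, class = "samlp_params")
}

#' Dense (affine + activation) layer
#'
#' @param h n x in matrix of inputs.
#' @param W in x out weight matrix.
#' @param b Length-out bias vector.
#' @param activation One of `"relu"`, `"none"`, `"sigmoid"`.
#' @return n x out matrix.
#' @export
dense_forward <- function(h, W, b, activation = c("none", "relu", "sigmoid")) {
  activation <- match.arg(activation)
  if (ncol(h) != nrow(W)) {
    stop_shape(sprintf("dense_forward: input has %d columns, weight expects %d",
                       ncol(h), nrow(W)))
  }
  z <- sweep(h %*% W, 2, b, "+")
  switch(activation,
         none = z,
         relu = pmax(z, 0),
         sigmoid = 1 / (1 + exp(-z)))
}

#' Scaled dot-product attention for one head
#'
#' `Softmax(Q K^T / sqrt(d_k)) V` over a token axis, with max-subtraction
#' for a numerically stable softmax. With a single token (T = 1) the weight
#' collapses to 1 and the output equals `V` exactly.
#'
#' @param Q,K,V T x key_dim matrices for one attention head.
#' @return T x key_dim matrix of attended values. The row-stochastic weight
#'   matrix is attached as attribute `"weights"`.
#' @export
scaled_dot_attention <- function(Q, K, V) {
  dk <- ncol(Q)
  if (dk == 0) stop_config("scaled_dot_attention: key_dim must be positive")
  if (!all(dim(Q) == dim(K)) || !all(dim(Q) == dim(V))) {
    stop_shape("scaled_dot_attention: Q, K, V must share dimensions")
  }
  scores <- Q %*% t(K) / sqrt(dk)
  m <- apply(scores, 1, max)
  expw <- exp(scores - m)
  A <- expw / rowSums(expw)
  structure(A %*% V, weights = A)
}

#' Multi-head self-attention over per-sample hidden vectors
#'
#' Q, K and V come from the dedicated dense projections of the hidden
#' representation; each is split along the channel axis into
#' `num_heads` heads of `key_dim` channels, attended per head, concatenated
#' and projected by the learned output matrix `WO`. Each sample's hidden
#' vector is one token (T = 1), so the per-head softmax weight is
#' identically 1 and the block reduces exactly to the V-projection followed
#' by the output projection — the Q/K paths carry no gradient in this mode.
#' The T = 1 computation is vectorized over samples; it is numerically
#' identical to calling [scaled_dot_attention()] per sample and head.
#'
#' @param h n x hidden matrix of hidden vectors.
#' @param params A [init_params()] result.
#' @param config A [samlp_config()].
#' @return n x hidden matrix.
#' @export
multi_head_attention <- function(h, params, config) {
  H <- config$hidden_dim
  if (ncol(h) != H) stop_shape("multi_head_attention: channel mismatch")
  Q <- dense_forward(h, params$WQ, params$bQ, "none")
  K <- dense_forward(h, params$WK, params$bK, "none")
  V <- dense_forward(h, params$WV, params$bV, "none")
  dk <- config$key_dim
  out <- matrix(0, nrow(h), H)
  for (i in seq_len(config$num_heads)) {
    cols <- ((i - 1) * dk + 1):(i * dk)
    # one token per sample: scores are n scalars, softmax of one element
    scores <- rowSums(Q[, cols, drop = FALSE] * K[, cols, drop = FALSE]) / sqrt(dk)
    weights <- exp(scores - scores) # == 1, written as the stabilized softmax
    out[, cols] <- weights * V[, cols, drop = FALSE]
  }
  dense_forward(out, params$WO, params$bO, "none")
}

#' Layer normalization
#'
#' Normalizes each row (sample) to zero mean and unit variance across
#' channels — variance with an `eps` guard so constant rows stay finite —
#' then applies the learned per-channel scale `gamma` and shift `beta`.
#'
#' @param h n x d matrix.
#' @param gamma,beta Length-d scale and shift vectors.
#' @param eps Positive variance guard.
#' @return n x d matrix.
#' @export
layer_norm <- function(h, gamma, beta, eps = 1e-3) {
  if (eps <= 0) stop_config("layer_norm: eps must be > 0")
  if (length(gamma) != ncol(h) || length(beta) != ncol(h)) {
    stop_shape("layer_norm: gamma/beta length must equal channel count")
  }
  mu <- rowMeans(h)
  centred <- h - mu
  v <- rowMeans(centred^2)
  xhat <- centred / sqrt(v + eps)
  sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
}

#' Full SA-MLP forward pass
#'
#' dense(ReLU) -> multi-head attention -> residual add + layer norm ->
#' dense(ReLU) -> dropout (training only) -> sigmoid head. With
#' `use_attention = FALSE` the hidden representation feeds layer
#' normalization directly (no attention, no residual duplication).
#'
#' @param X n x input_dim numeric matrix (standardized features).
#' @param params A [init_params()] result.
#' @param config A [samlp_config()].
#' @param training If `TRUE`, apply inverted dropout (a fresh Bernoulli mask
#'   from the current RNG state); inference is deterministic.
#' @return Length-n vector of probabilities strictly inside (0, 1). The
#'   intermediate activations are attached as attribute `"cache"` when
#'   `keep_cache = TRUE`.
#' @param keep_cache Keep intermediate activations (used by backprop).
#' @export
samlp_forward <- function(X, params, config, training = FALSE, keep_cache = FALSE) {
  if (ncol(X) != config$input_dim) {
    stop_shape(sprintf("forward: X has %d columns, config expects %d",
                       ncol(X), config$input_dim))
  }
  pre1 <- sweep(X %*% params$W1, 2, params$b1, "+")
  h1 <- pmax(pre1, 0)
  if (config$use_attention) {
    attn <- multi_head_attention(h1, params, config)
    a <- h1 + attn
  } else {
    a <- h1
  }
  # layer norm with cached normalizers for the backward pass
  mu <- rowMeans(a)
  centred <- a - mu
  v <- rowMeans(centred^2)
  invstd <- 1 / sqrt(v + config$layernorm_eps)
  xhat <- centred * invstd
  z <- sweep(sweep(xhat, 2, params$gamma, "*"), 2, params$beta, "+")
  pre2 <- sweep(z %*% params$W2, 2, params$b2, "+")
  h2 <- pmax(pre2, 0)
  if (training && config$dropout_rate > 0) {
    keep <- 1 - config$dropout_rate
    mask <- matrix(stats::rbinom(length(h2), 1, keep) / keep, nrow(h2))
  } else {
    mask <- NULL
  }
  h2d <- if (is.null(mask)) h2 else h2 * mask
  logit <- drop(h2d %*% params$W3) + params$b3
  prob <- 1 / (1 + exp(-logit))
  if (any(!is.finite(prob))) {
    abort("forward pass produced non-finite probabilities (divergence?)",
          class = "voicerisk_numerical_error")
  }
  if (keep_cache) {
    attr(prob, "cache") <- list(X = X, pre1 = pre1, h1 = h1, xhat = xhat,
                                invstd = invstd, z = z, pre2 = pre2, h2 = h2,
                                mask = mask, logit = logit)
  }
  prob
}

#' Binary cross-entropy loss
#'
#' Mean of `-[y log(p) + (1 - y) log(1 - p)]` with probabilities clipped
#' into `[eps, 1 - eps]` to avoid `log(0)`.
#'
#' @param y Binary vector of labels.
#' @param yhat Probability vector of the same length.
#' @param eps Clipping constant (default 1e-7).
#' @return Non-negative scalar.
#' @export
bce_loss <- function(y, yhat, eps = 1e-7) {
  if (length(y) != length(yhat)) stop_shape("bce_loss: length mismatch")
  p <- pmin(pmax(yhat, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
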