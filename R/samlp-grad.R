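# Manual backpropagation for the SA-MLP. Gradients are for the mean BCE
# loss of the forward pass; the loss's probability clip is a numerical
# guard at saturation and is not differentiated through.

samlp_backprop <- function(X, y, params, config, training = FALSE) {
  prob <- samlp_forward(X, params, config, training = training, keep_cache = TRUE)
  cache <- attr(prob, "cache")
  p <- as.numeric(prob)
  n <- length(y)
  loss <- bce_loss(y, p)

  g <- list()
  dlogit <- matrix((p - y) / n, ncol = 1)
  h2d <- if (is.null(cache$mask)) cache$h2 else cache$h2 * cache$mask
  g$W3 <- t(h2d) %*% dlogit
  g$b3 <- sum(dlogit)
  dh2d <- dlogit %*% t(params$W3)
  dh2 <- if (is.null(cache$mask)) dh2d else dh2d * cache$mask
  dpre2 <- dh2 * (cache$pre2 > 0)
  g$W2 <- t(cache$z) %*% dpre2
  g$b2 <- colSums(dpre2)
  dz <- dpre2 %*% t(params$W2)

  # layer norm backward (per-row statistics)
  g$gamma <- colSums(dz * cache$xhat)
  g$beta <- colSums(dz)
  dxhat <- sweep(dz, 2, params$gamma, "*")
  da <- (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat)) *
    cache$invstd

  if (config$use_attention) {
    dh1 <- da # residual branch
    dattn <- da
    # T = 1 attention: out = (h1 WV + bV) WO + bO; softmax weight constant 1,
    # so the Q/K projections receive exactly zero gradient.
    V <- dense_forward(cache$h1, params$WV, params$bV, "none")
    g$WO <- t(V) %*% dattn
    g$bO <- colSums(dattn)
    dV <- dattn %*% t(params$WO)
    g$WV <- t(cache$h1) %*% dV
    g$bV <- colSums(dV)
    dh1 <- dh1 + dV %*% t(params$WV)
    g$WQ <- matrix(0, nrow(params$WQ), ncol(params$WQ))
    g$bQ <- numeric(length(params$bQ))
    g$WK <- matrix(0, nrow(params$WK), ncol(params$WK))
    g$bK <- numeric(length(params$bK))
  } else {
    dh1 <- da
  }

  dpre1 <- dh1 * (cache$pre1 > 0)
  g$W1 <- t(cache$X) %*% dpre1
  g$b1 <- colSums(dpre1)

  list(loss = loss, grads = g[names(params)[names(params) %in% names(g)]],
       prob = p)
}

#' Finite-difference check of the analytic gradients
#'
#' Compares the backpropagated gradient of the mean BCE loss with central
#' finite differences, tensor by tensor, on a random instance. The relative
#' error per tensor is `max|analytic - numeric| / max(1, max|analytic|,
#' max|numeric|)`; the unit guard keeps the measure meaningful for the Q/K
#' projections, whose analytic gradient is exactly zero in the single-token
#' attention mode.
#'
#' The loss is only piecewise differentiable (ReLU kinks), and with
#' zero-initialized biases an all-negative hidden row sits exactly on a
#' kink, where central differences straddle two linear pieces and measure
#' nothing. Instances are therefore redrawn (deterministically from the
#' seed) until every pre-activation is at least `100 * h` away from zero.
#'
#' @param config A [samlp_config()]; defaults to a tiny model so the check
#'   is fast.
#' @param n Number of random samples in the instance.
#' @param seed Seed for instance and initialization.
#' @param h Finite-difference step.
#' @return A tibble with columns `tensor`, `max_analytic`, `max_numeric`,
#'   `rel_err`.
#' @export
#' @examples
#' chk <- gradient_check(seed = 1)
#' all(chk$rel_err <= 1e-4)
gradient_check <- function(config = samlp_config(input_dim = 3L, hidden_dim = 4L,
                                                 num_heads = 2L, key_dim = 2L,
                                                 dense2_dim = 2L, dropout_rate = 0),
                           n = 5L, seed = 1L, h = 1e-5) {
  margin <- 100 * h
  for (attempt in seq_len(50L)) {
    set.seed((seed + (attempt - 1L) * 101L) %% 2147483647L)
    X <- matrix(rnorm(n * config$input_dim), n)
    y <- stats::rbinom(n, 1, 0.5)
    params <- init_params(config, seed = (seed + attempt) %% 2147483647L)
    cache <- attr(samlp_forward(X, params, config, keep_cache = TRUE), "cache")
    if (min(abs(cache$pre1)) > margin && min(abs(cache$pre2)) > margin) break
    if (attempt == 50L) {
      stop_value("gradient_check: no kink-free instance found in 50 draws")
    }
  }
  bp <- samlp_backprop(X, y, params, config, training = FALSE)

  loss_at <- function(p) bce_loss(y, samlp_forward(X, p, config, training = FALSE))
  purrr::map_dfr(names(bp$grads), function(nm) {
    analytic <- bp$grads[[nm]]
    numeric_g <- analytic
    for (i in seq_along(params[[nm]])) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
      numeric_g[i] <- (loss_at(pp) - loss_at(pm)) / (2 * h)
    }
    denom <- max(1, max(abs(analytic)), max(abs(numeric_g)))
    tibble::tibble(tensor = nm,
                   max_analytic = max(abs(analytic)),
                   max_numeric = max(abs(numeric_g)),
                   rel_err = max(abs(analytic - numeric_g)) / denom)
  })
}
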