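# Internal multilayer-perceptron machinery for the VAE engine.
#
# No automatic differentiation is used anywhere: each layer's gradients are
# written out analytically and checked against finite differences in the test
# suite. Weights are stored input x output so a batch (rows = samples)
# propagates as X %*% W + b.

nn_glorot <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
}

# trunk of `length(sizes)-1` tanh layers (the final head layers are linear and
# owned by the encoder/decoder wrappers)
nn_init_trunk <- function(sizes) {
  purrr::map(seq_len(length(sizes) - 1L), function(i) {
    list(W = nn_glorot(sizes[i], sizes[i + 1L]), b = rep(0, sizes[i + 1L]))
  })
}

nn_trunk_forward <- function(trunk, X) {
  acts <- vector("list", length(trunk) + 1L)
  acts[[1L]] <- X
  for (i in seq_along(trunk)) {
    acts[[i + 1L]] <- tanh(sweep(acts[[i]] %*% trunk[[i]]$W, 2L, trunk[[i]]$b, "+"))
  }
  acts
}

# dH: gradient w.r.t. trunk output. Returns per-layer grads plus dX.
nn_trunk_backward <- function(trunk, acts, dH) {
  grads <- vector("list", length(trunk))
  for (i in rev(seq_along(trunk))) {
    dA <- dH * (1 - acts[[i + 1L]]^2)      # tanh'
    grads[[i]] <- list(W = crossprod(acts[[i]], dA), b = colSums(dA))
    dH <- dA %*% t(trunk[[i]]$W)
  }
  list(grads = grads, dX = dH)
}

# ---- Adam ------------------------------------------------------------------
# params/grads are arbitrarily nested lists of numeric arrays with identical
# shape; state holds first/second moments and the step counter.

adam_init <- function(params) {
  zeros <- rapply(params, function(p) array(0, dim = dim(p) %||% length(p)),
                  how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  flat_p <- rapply(params, identity, how = "unlist")
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- purrr::pmap(list(p, g, m, v), walk)
      list(p = purrr::map(out, "p"), m = purrr::map(out, "m"),
           v = purrr::map(out, "v"))
    } else {
      upd(p, g, m, v)
    }
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically stable -log p for Bernoulli with logit a: softplus(a) - x*a
bernoulli_nll_logit <- function(a, x) {
  pmax(a, 0) - x * a + log1p(exp(-abs(a)))
}

row_softmax <- function(A) {
  E <- exp(A - apply(A, 1L, max))
  E / rowSums(E)
}
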