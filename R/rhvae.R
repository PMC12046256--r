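#' Configuration of the geometry-based VAE
#'
#' Default training schedule: 1000 epochs, batch size 32, learning rate
#' 0.001. Architecture and geometry settings are package defaults sized for
#' high-dimension low-sample-size tabular cohorts; everything is
#' overridable.
#'
#' @param latent_dim Latent dimension d_z.
#' @param hidden Encoder trunk widths (the decoder mirrors them reversed).
#' @param epochs,batch_size,learning_rate Optimization schedule (Adam, no
#'   scheduler, no early stopping).
#' @param n_leapfrog_steps Leapfrog steps of Riemannian-Hamiltonian posterior
#'   refinement per minibatch (0 disables refinement, reducing the engine to
#'   a vanilla VAE).
#' @param leapfrog_step_size Integration step of the refinement.
#' @param metric_temperature Kernel bandwidth T of the learned metric.
#' @param metric_regularization Regularization floor λ of the learned metric.
#' @param n_metric_centroids Number of metric centroids (default: training-set
#'   size, capped at 400).
#' @param kl_warmup_epochs Epochs over which the KL term's weight ramps
#'   linearly from 0 to 1 (0 disables warm-up). Warm-up counteracts early
#'   posterior collapse on small cohorts.
#' @param seed One seed controls weight initialization, batch shuffling, and
#'   all momentum/posterior draws.
#' @return An `rhvae_config` list.
#' @export
rhvae_config <- function(latent_dim = 10, hidden = c(64, 32), epochs = 1000,
                         batch_size = 32, learning_rate = 0.001,
                         n_leapfrog_steps = 3, leapfrog_step_size = 0.01,
                         metric_temperature = 0.8, metric_regularization = 1e-3,
                         n_metric_centroids = NULL, kl_warmup_epochs = 0,
                         seed = 1) {
  stopifnot(latent_dim >= 1, all(hidden >= 1), epochs >= 1, batch_size >= 1,
            learning_rate > 0, n_leapfrog_steps >= 0, leapfrog_step_size > 0,
            metric_temperature > 0, metric_regularization > 0,
            kl_warmup_epochs >= 0)
  structure(
    list(latent_dim = as.integer(latent_dim), hidden = as.integer(hidden),
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate,
         n_leapfrog_steps = as.integer(n_leapfrog_steps),
         leapfrog_step_size = leapfrog_step_size,
         metric_temperature = metric_temperature,
         metric_regularization = metric_regularization,
         n_metric_centroids = n_metric_centroids,
         kl_warmup_epochs = as.integer(kl_warmup_epochs),
         seed = as.integer(seed)),
    class = "rhvae_config"
  )
}

# encoded-column roles derived from an encoded_cohort's column map
encoded_roles <- function(column_map) {
  role <- column_map$role
  blocks <- split(which(role == "one-hot"), column_map$source[role == "one-hot"])
  list(
    idx_num = which(role == "scaled-numeric"),
    idx_bin = which(role == "binary"),
    blocks = unname(blocks[unique(column_map$source[role == "one-hot"])])
  )
}

encoder_forward <- function(enc, X) {
  acts <- nn_trunk_forward(enc$trunk, X)
  H <- acts[[length(acts)]]
  mu <- sweep(H %*% enc$W_mu, 2L, enc$b_mu, "+")
  lv_pre <- sweep(H %*% enc$W_lv, 2L, enc$b_lv, "+")
  lv <- pmin(pmax(lv_pre, -8), 8)
  list(mu = mu, lv = lv, lv_mask = (abs(lv_pre) < 8) * 1, acts = acts)
}

decoder_forward <- function(dec, Z) {
  acts <- nn_trunk_forward(dec$trunk, Z)
  H <- acts[[length(acts)]]
  A <- sweep(H %*% dec$W_out, 2L, dec$b_out, "+")
  list(A = A, acts = acts)
}

# decoder raw scores -> per-coordinate distribution parameters in (0, 1)
decoder_probs <- function(A, roles) {
  P <- A
  sig_idx <- c(roles$idx_num, roles$idx_bin)
  if (length(sig_idx)) P[, sig_idx] <- sigmoid(A[, sig_idx, drop = FALSE])
  for (blk in roles$blocks) P[, blk] <- row_softmax(A[, blk, drop = FALSE])
  P
}

# per-sample reconstruction negative log-likelihood and gradient w.r.t. raw
# decoder scores; Gaussian(learned sigma) for scaled numerics, Bernoulli for
# binaries, categorical for one-hot blocks
recon_nll <- function(A, X, roles, log_sigma, grad = TRUE) {
  n <- nrow(A)
  nll <- numeric(n)
  dA <- if (grad) matrix(0, n, ncol(A)) else NULL
  dls <- if (grad) numeric(length(roles$idx_num)) else NULL
  if (length(roles$idx_num)) {
    # censored (Tobit) Gaussian on [0, 1]: min-max scaling clips values at the
    # bounds, so boundary observations are censoring events, not exact values
    m <- sigmoid(A[, roles$idx_num, drop = FALSE])
    x <- X[, roles$idx_num, drop = FALSE]
    s <- exp(log_sigma)
    S <- matrix(s, nrow(m), ncol(m), byrow = TRUE)
    at0 <- x <= 0
    at1 <- x >= 1
    mid <- !(at0 | at1)
    zres <- (x - m) / S
    term <- matrix(0, nrow(m), ncol(m))
    term[mid] <- 0.5 * zres[mid]^2 +
      (matrix(log_sigma, nrow(m), ncol(m), byrow = TRUE) + 0.5 * log(2 * pi))[mid]
    # lower tail: -log P(m + eps <= 0); upper tail: -log P(m + eps >= 1)
    u0 <- -m / S
    v1 <- (m - 1) / S
    term[at0] <- -stats::pnorm(u0[at0], log.p = TRUE)
    term[at1] <- -stats::pnorm(v1[at1], log.p = TRUE)
    nll <- nll + rowSums(term)
    if (grad) {
      dm <- matrix(0, nrow(m), ncol(m))
      dls_m <- matrix(0, nrow(m), ncol(m))
      dm[mid] <- ((m - x) / S^2)[mid]
      dls_m[mid] <- (1 - zres^2)[mid]
      # inverse Mills ratios, computed in log space for stability
      r0 <- exp(stats::dnorm(u0, log = TRUE) - stats::pnorm(u0, log.p = TRUE))
      r1 <- exp(stats::dnorm(v1, log = TRUE) - stats::pnorm(v1, log.p = TRUE))
      dm[at0] <- (r0 / S)[at0]
      dls_m[at0] <- (u0 * r0)[at0]
      dm[at1] <- (-r1 / S)[at1]
      dls_m[at1] <- (v1 * r1)[at1]
      dA[, roles$idx_num] <- dm * m * (1 - m)
      dls <- colSums(dls_m)
    }
  }
  if (length(roles$idx_bin)) {
    a <- A[, roles$idx_bin, drop = FALSE]
    x <- X[, roles$idx_bin, drop = FALSE]
    nll <- nll + rowSums(bernoulli_nll_logit(a, x))
    if (grad) dA[, roles$idx_bin] <- sigmoid(a) - x
  }
  for (blk in roles$blocks) {
    a <- A[, blk, drop = FALSE]
    x <- X[, blk, drop = FALSE]
    amax <- apply(a, 1L, max)
    lse <- amax + log(rowSums(exp(a - amax)))
    nll <- nll + lse - rowSums(x * a)
    if (grad) dA[, blk] <- exp(a - lse) - x
  }
  list(nll = nll, dA = dA, dlog_sigma = dls)
}

# gradient of the per-sample potential U(z) = recon NLL + 0.5||z||^2 w.r.t. z
grad_potential_batch <- function(dec, log_sigma, roles, X, Z) {
  fwd <- decoder_forward(dec, Z)
  rec <- recon_nll(fwd$A, X, roles, log_sigma, grad = TRUE)
  bwd <- nn_trunk_backward(dec$trunk, fwd$acts, rec$dA %*% t(dec$W_out))
  bwd$dX + Z
}

# vectorized diagonal-metric quantities for a batch of latent rows
batch_metric_ginv <- function(metric, Z) {
  K <- metric_kernel(metric, Z)
  list(K = K, Ginv = K %*% metric$Mdiag + metric$lambda)
}

# grad_z of the kinetic + log-volume Hamiltonian terms, batch, diagonal metric
batch_metric_grad_z <- function(metric, Z, P2, km) {
  W <- km$K * (P2 %*% t(metric$Mdiag) - (1 / km$Ginv) %*% t(metric$Mdiag))
  (W %*% metric$centroids - Z * rowSums(W)) / metric$temperature^2
}

# Riemannian-Hamiltonian refinement of a batch of posterior draws (diagonal
# metric fast path; cross-checked against leapfrog_integrate in the tests)
refine_latent_batch <- function(dec, log_sigma, roles, X, Z, metric, steps,
                                step_size, fp_tol = 1e-10, fp_max_iter = 20L) {
  if (steps == 0L) return(Z)
  h <- step_size / 2
  km <- batch_metric_ginv(metric, Z)
  P <- matrix(stats::rnorm(length(Z)), nrow(Z)) / sqrt(km$Ginv)  # p ~ N(0, G(z))
  gU <- grad_potential_batch(dec, log_sigma, roles, X, Z)
  for (s in seq_len(steps)) {
    P1 <- P
    for (it in seq_len(fp_max_iter)) {
      Pn <- P - h * (gU + batch_metric_grad_z(metric, Z, P1^2, km))
      if (max(abs(Pn - P1)) < fp_tol) { P1 <- Pn; break }
      P1 <- Pn
    }
    gp_old <- km$Ginv * P1
    Z1 <- Z
    for (it in seq_len(fp_max_iter)) {
      km1 <- batch_metric_ginv(metric, Z1)
      Zn <- Z + h * (gp_old + km1$Ginv * P1)
      if (max(abs(Zn - Z1)) < fp_tol) { Z1 <- Zn; break }
      Z1 <- Zn
    }
    Z <- Z1
    km <- batch_metric_ginv(metric, Z)
    gU <- grad_potential_batch(dec, log_sigma, roles, X, Z)
    P <- P1 - h * (gU + batch_metric_grad_z(metric, Z, P1^2, km))
    if (!all(is.finite(Z))) {
      stop("non-finite latent position during Hamiltonian refinement",
           call. = FALSE)
    }
  }
  Z
}

#' Train the geometry-based VAE on an encoded cohort
#'
#' Optimizes a variational objective — role-aware reconstruction likelihood
#' (Gaussian with learned per-coordinate noise for scaled numerics, Bernoulli
#' for binaries, categorical for one-hot blocks) plus the standard normal-prior
#' KL term — jointly over encoder, decoder and observation-noise parameters
#' with Adam. A Riemannian metric over the latent space is learned alongside:
#' centroids track the posterior means of a training subsample by exponential
#' moving average, the (diagonal) triangular factors track the corresponding
#' inverse posterior variances, and after a short warm-up each minibatch's
#' posterior draw is refined by generalized-leapfrog Hamiltonian dynamics
#' under that metric before reconstruction. With `n_leapfrog_steps = 0` the
#' engine is exactly a vanilla VAE.
#'
#' @param encoded An `encoded_cohort` from [fit_transform()].
#' @param config An [rhvae_config()].
#' @return An `rhvae_fit` holding encoder/decoder weights, the learned
#'   [riemannian_metric()], the per-epoch `training_log` (tibble: epoch, loss,
#'   recon, kl) and the decoding sidecar (column map, scaler state, schema).
#'   Fixed seed implies a bit-reproducible training log on the same platform.
#' @export
rhvae <- function(encoded, config = rhvae_config()) {
  stopifnot(inherits(encoded, "encoded_cohort"), inherits(config, "rhvae_config"))
  X <- encoded$values
  n <- nrow(X); d <- ncol(X)
  if (config$batch_size > n) {
    stop("batch_size (", config$batch_size, ") exceeds the number of rows (",
         n, ")", call. = FALSE)
  }
  roles <- encoded_roles(encoded$column_map)
  dz <- config$latent_dim
  set.seed(config$seed)

  enc <- list(trunk = nn_init_trunk(c(d, config$hidden)),
              W_mu = nn_glorot(utils::tail(config$hidden, 1L), dz), b_mu = rep(0, dz),
              W_lv = nn_glorot(utils::tail(config$hidden, 1L), dz), b_lv = rep(0, dz))
  dec <- list(trunk = nn_init_trunk(c(dz, rev(config$hidden))),
              W_out = nn_glorot(config$hidden[1L], d), b_out = rep(0, d))
  log_sigma <- rep(log(0.1), length(roles$idx_num))

  params <- list(enc = enc, dec = dec, log_sigma = log_sigma)
  opt <- adam_init(params)

  n_cent <- min(n, config$n_metric_centroids %||% 400L)
  cent_idx <- sample.int(n, n_cent)
  metric <- NULL
  warmup <- 10L
  ema <- 0.1

  log_rows <- matrix(NA_real_, config$epochs, 3L)
  n_batches <- floor(n / config$batch_size)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    ep_loss <- ep_rec <- ep_kl <- 0
    for (b in seq_len(n_batches)) {
      idx <- perm[((b - 1L) * config$batch_size + 1L):(b * config$batch_size)]
      Xb <- X[idx, , drop = FALSE]
      B <- nrow(Xb)
      ef <- encoder_forward(params$enc, Xb)
      eps <- matrix(stats::rnorm(B * dz), B, dz)
      sd_z <- exp(0.5 * ef$lv)
      Z <- ef$mu + sd_z * eps
      Zu <- if (!is.null(metric) && epoch > warmup && config$n_leapfrog_steps > 0L) {
        refine_latent_batch(params$dec, params$log_sigma, roles, Xb, Z, metric,
                            config$n_leapfrog_steps, config$leapfrog_step_size)
      } else {
        Z
      }
      df <- decoder_forward(params$dec, Zu)
      rec <- recon_nll(df$A, Xb, roles, params$log_sigma, grad = TRUE)
      kl <- 0.5 * rowSums(ef$mu^2 + exp(ef$lv) - 1 - ef$lv)
      beta <- if (config$kl_warmup_epochs > 0) {
        min(1, epoch / config$kl_warmup_epochs)
      } else 1
      loss <- mean(rec$nll + kl)
      if (!is.finite(loss)) {
        stop("non-finite loss at epoch ", epoch, ", batch ", b, call. = FALSE)
      }
      ep_loss <- ep_loss + loss
      ep_rec <- ep_rec + mean(rec$nll)
      ep_kl <- ep_kl + mean(kl)

      dA <- rec$dA / B
      dbwd <- nn_trunk_backward(params$dec$trunk, df$acts, dA %*% t(params$dec$W_out))
      dec_grads <- list(trunk = dbwd$grads,
                        W_out = crossprod(df$acts[[length(df$acts)]], dA),
                        b_out = colSums(dA))
      dZ <- dbwd$dX
      # gradient pass-through: the refined point feeds the decoder; the
      # encoder receives the reparameterization gradient at the raw draw
      dmu <- dZ + beta * ef$mu / B
      dlv <- (dZ * 0.5 * sd_z * eps + beta * 0.5 * (exp(ef$lv) - 1) / B) * ef$lv_mask
      H <- ef$acts[[length(ef$acts)]]
      dH <- dmu %*% t(params$enc$W_mu) + dlv %*% t(params$enc$W_lv)
      ebwd <- nn_trunk_backward(params$enc$trunk, ef$acts, dH)
      enc_grads <- list(trunk = ebwd$grads,
                        W_mu = crossprod(H, dmu), b_mu = colSums(dmu),
                        W_lv = crossprod(H, dlv), b_lv = colSums(dlv))
      grads <- list(enc = enc_grads, dec = dec_grads,
                    log_sigma = rec$dlog_sigma / B)
      st <- adam_step(params, grads, opt, config$learning_rate)
      params <- st$params
      params$log_sigma <- pmin(pmax(params$log_sigma, -5), 2)
      opt <- st$state
    }
    # update the learned metric from the centroid subsample's posteriors
    cf <- encoder_forward(params$enc, X[cent_idx, , drop = FALSE])
    inv_var <- exp(-cf$lv)
    if (is.null(metric)) {
      cent <- cf$mu; minv <- inv_var
    } else {
      cent <- (1 - ema) * metric$centroids + ema * cf$mu
      minv <- (1 - ema) * metric$Mdiag + ema * inv_var
    }
    metric <- riemannian_metric(cent, sqrt(minv),
                                temperature = config$metric_temperature,
                                lambda = config$metric_regularization)
    log_rows[epoch, ] <- c(ep_loss, ep_rec, ep_kl) / n_batches
  }

  structure(
    list(encoder = params$enc, decoder = params$dec,
         log_sigma = as.numeric(params$log_sigma), metric = metric,
         roles = roles,
         config = config,
         training_log = tibble::tibble(epoch = seq_len(config$epochs),
                                       loss = log_rows[, 1L],
                                       recon = log_rows[, 2L],
                                       kl = log_rows[, 3L]),
         sidecar = list(column_map = encoded$column_map,
                        scaler_state = encoded$scaler_state,
                        schema = encoded$schema),
         n_train = n),
    class = "rhvae_fit"
  )
}

#' Evaluate the variational objective on a fixed batch
#'
#' Computes the negative ELBO (reconstruction negative log-likelihood plus
#' KL to the standard-normal prior, averaged over the batch) for given noise
#' draws, without any Hamiltonian refinement. Deterministic given `eps`; used
#' to verify that the engine with identity metric and zero leapfrog steps is
#' exactly a vanilla VAE.
#'
#' @param fit An `rhvae_fit`.
#' @param x Batch matrix (rows in encoded [0,1] space).
#' @param eps Standard-normal noise matrix, same rows as `x`, `latent_dim`
#'   columns.
#' @return List with `loss` (negative ELBO), `recon`, `kl`, and the latent
#'   draw `z`.
#' @export
rhvae_objective <- function(fit, x, eps) {
  stopifnot(inherits(fit, "rhvae_fit"))
  x <- as.matrix(x)
  ef <- encoder_forward(fit$encoder, x)
  z <- ef$mu + exp(0.5 * ef$lv) * eps
  df <- decoder_forward(fit$decoder, z)
  rec <- recon_nll(df$A, x, fit$roles, fit$log_sigma, grad = FALSE)
  kl <- 0.5 * rowSums(ef$mu^2 + exp(ef$lv) - 1 - ef$lv)
  list(loss = mean(rec$nll + kl), recon = mean(rec$nll), kl = mean(kl), z = z)
}

#' @export
print.rhvae_fit <- function(x, ...) {
  cat("<rhvae_fit> trained on ", x$n_train, " x ",
      nrow(x$sidecar$column_map), " encoded cohort; latent dim ",
      x$config$latent_dim, ", ", x$config$epochs, " epochs (final loss ",
      format(utils::tail(x$training_log$loss, 1L), digits = 5), ")\n", sep = "")
  invisible(x)
}

#' Broom-style accessors for a trained model
#'
#' `tidy()` returns the per-epoch training log; `glance()` a one-row model
#' summary.
#'
#' @param x An `rhvae_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rhvae_fit <- function(x, ...) x$training_log

#' @rdname tidy.rhvae_fit
#' @export
glance.rhvae_fit <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train,
    encoded_width = nrow(x$sidecar$column_map),
    latent_dim = x$config$latent_dim,
    epochs = x$config$epochs,
    n_centroids = nrow(x$metric$centroids),
    initial_loss = x$training_log$loss[1L],
    final_loss = utils::tail(x$training_log$loss, 1L)
  )
}
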