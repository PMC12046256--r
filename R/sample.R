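#' Sample latent points from a trained model
#'
#' The default `"metric-walk"` sampler explores the learned latent manifold
#' with a Metropolis random walk over the metric's local volume measure: the
#' mixture density in which each metric centroid \eqn{c_i} spreads its mass
#' according to the local metric tensor \eqn{G(c_i) = (M_i + \lambda I)^{-1}},
#' \deqn{\rho(z) \propto \sum_i \sqrt{\det(M_i + \lambda I)}\,
#'   \exp\!\big(-\tfrac12 (z - c_i)^\top (M_i + \lambda I)(z - c_i)\big),}
#' i.e. an equal-weight mixture of Gaussians whose covariances are the learned
#' metric at the centroids. Under the learned metric \eqn{G^{-1}(z)} is large
#' exactly where the training data live, so this measure concentrates samples
#' on the supported manifold, spread the way the geometry says the manifold
#' extends locally. (Taking the determinant of the *summed* \eqn{G^{-1}}
#' instead would raise every kernel overlap to the \eqn{d_z/2} power and
#' collapse the mass onto the densest point of the centroid cloud; the
#' per-centroid volume measure avoids that pathology and has an exact
#' mixture form.) Each sample starts its own chain at an exact draw from the
#' mixture, so the walk is stationary from the first step, and uses a
#' counter-based per-sample seed so results are independent of any chunking
#' of the request.
#' The `"prior-gaussian"` sampler draws from the standard-normal prior and is
#' retained as an ablation baseline.
#'
#' @param fit An `rhvae_fit` (or, for `sample_metric_walk()`, a bare
#'   [riemannian_metric()]).
#' @param n_samples Number of latent points.
#' @param seed Integer seed; identical seeds give identical samples.
#' @param sampler `"metric-walk"` (default) or `"prior-gaussian"`.
#' @param n_steps,proposal_sd Chain length and random-walk proposal scale of
#'   the metric walk (proposal defaults to half the typical per-centroid
#'   local standard deviation).
#' @return `n_samples` x `latent_dim` matrix.
#' @export
sample_latent <- function(fit, n_samples, seed = 1,
                          sampler = c("metric-walk", "prior-gaussian"),
                          n_steps = 30L, proposal_sd = NULL) {
  stopifnot(inherits(fit, "rhvae_fit"), n_samples >= 0)
  sampler <- match.arg(sampler)
  dz <- fit$config$latent_dim
  if (n_samples == 0L) return(matrix(numeric(0), 0L, dz))
  if (sampler == "prior-gaussian") {
    set.seed(seed)
    return(matrix(stats::rnorm(n_samples * dz), n_samples, dz))
  }
  if (is.null(fit$metric)) stop("model has no learned metric", call. = FALSE)
  sample_metric_walk(fit$metric, n_samples, seed, n_steps = n_steps,
                     proposal_sd = proposal_sd)
}

# deterministic per-sample sub-seed (kept below 2^31)
sample_seed <- function(seed, i, salt = 0L) {
  (as.numeric(seed) * 69069 + i * 104729 + salt * 7919) %% 2147483629
}

# per-centroid precision representation of the local mixture: for each
# centroid the precision M_i + lambda I, its Cholesky factor (for exact
# draws) and log-normalizer 0.5 log det(M_i + lambda I)
metric_local_components <- function(metric) {
  dz <- ncol(metric$centroids)
  K <- nrow(metric$centroids)
  if (metric$diag) {
    prec <- metric$Mdiag + metric$lambda
    list(diag = TRUE, prec = prec, sd = 1 / sqrt(prec),
         logdet_half = 0.5 * rowSums(log(prec)))
  } else {
    chols <- vector("list", K)
    for (i in seq_len(K)) {
      chols[[i]] <- chol(matrix(metric$Mflat[i, ], dz, dz) +
                           metric$lambda * diag(dz))
    }
    list(diag = FALSE, chols = chols,
         logdet_half = vapply(chols, function(U) sum(log(diag(U))), numeric(1)))
  }
}

# log density (up to a constant) of the local volume mixture at rows of Z
metric_walk_log_density <- function(metric, Z, comp) {
  C <- metric$centroids
  K <- nrow(C)
  n <- nrow(Z)
  if (comp$diag) {
    # quadratic forms (z - c_i)' diag(prec_i) (z - c_i) for all pairs
    Q <- Z^2 %*% t(comp$prec) - 2 * Z %*% t(C * comp$prec) +
      matrix(rowSums(C^2 * comp$prec), n, K, byrow = TRUE)
  } else {
    Q <- matrix(0, n, K)
    for (i in seq_len(K)) {
      D <- sweep(Z, 2L, C[i, ])
      Q[, i] <- rowSums((D %*% t(comp$chols[[i]]))^2)
    }
  }
  S <- sweep(-0.5 * Q, 2L, comp$logdet_half, "+")
  mx <- apply(S, 1L, max)
  mx + log(rowSums(exp(S - mx)))
}

#' @rdname sample_latent
#' @param metric A [riemannian_metric()].
#' @export
sample_metric_walk <- function(metric, n_samples, seed = 1, n_steps = 30L,
                               proposal_sd = NULL) {
  stopifnot(inherits(metric, "riemannian_metric"), n_samples >= 0, n_steps >= 1)
  dz <- ncol(metric$centroids)
  if (n_samples == 0L) return(matrix(numeric(0), 0L, dz))
  K <- nrow(metric$centroids)
  comp <- metric_local_components(metric)
  typical_sd <- if (comp$diag) {
    stats::median(comp$sd)
  } else {
    stats::median(exp(-comp$logdet_half / dz))
  }
  prop_sd <- proposal_sd %||% (typical_sd / 2)
  # pre-draw every random number with counter-based per-sample seeds so that
  # generating in chunks cannot change the result
  start_idx <- integer(n_samples)
  start_noise <- matrix(0, n_samples, dz)
  prop <- array(0, c(n_samples, dz, n_steps))
  logu <- matrix(0, n_samples, n_steps)
  for (i in seq_len(n_samples)) {
    set.seed(sample_seed(seed, i))
    start_idx[i] <- sample.int(K, 1L)
    start_noise[i, ] <- stats::rnorm(dz)
    prop[i, , ] <- stats::rnorm(dz * n_steps, sd = prop_sd)
    logu[i, ] <- log(stats::runif(n_steps))
  }
  # exact mixture draw: the chain starts in its stationary distribution
  Z <- metric$centroids[start_idx, , drop = FALSE]
  if (comp$diag) {
    Z <- Z + start_noise * comp$sd[start_idx, , drop = FALSE]
  } else {
    for (i in seq_len(n_samples)) {
      Z[i, ] <- Z[i, ] + backsolve(comp$chols[[start_idx[i]]], start_noise[i, ])
    }
  }
  lp <- metric_walk_log_density(metric, Z, comp)
  for (t in seq_len(n_steps)) {
    Zp <- Z + prop[, , t, drop = TRUE]
    if (n_samples == 1L) Zp <- matrix(Zp, 1L)
    lpp <- metric_walk_log_density(metric, Zp, comp)
    acc <- logu[, t] < (lpp - lp)
    Z[acc, ] <- Zp[acc, , drop = FALSE]
    lp[acc] <- lpp[acc]
  }
  Z
}

#' Generate an artificial patient cohort
#'
#' Samples latent points (see [sample_latent()]), decodes them through the
#' trained decoder, draws each encoded coordinate from its decoded
#' distribution (Gaussian with the learned observation noise for scaled
#' numerics, Bernoulli for binary columns, categorical within each one-hot
#' block), and inverse-transforms the result into a schema-valid patient
#' table. All randomness is controlled by `seed` with counter-based
#' per-sample sub-seeds.
#'
#' @inheritParams sample_latent
#' @return A schema-conforming tibble with exactly `n_samples` rows.
#' @export
generate_cohort <- function(fit, n_samples, seed = 1,
                            sampler = c("metric-walk", "prior-gaussian")) {
  stopifnot(inherits(fit, "rhvae_fit"), n_samples >= 0)
  sampler <- match.arg(sampler)
  sc <- fit$sidecar
  template <- structure(
    list(values = NULL, column_map = sc$column_map,
         scaler_state = sc$scaler_state, schema = sc$schema),
    class = "encoded_cohort"
  )
  if (n_samples == 0L) {
    empty <- matrix(numeric(0), 0L, nrow(sc$column_map))
    return(inverse_transform(template, empty))
  }
  Z <- sample_latent(fit, n_samples, seed = seed, sampler = sampler)
  P <- decoder_probs(decoder_forward(fit$decoder, Z)$A, fit$roles)
  roles <- fit$roles
  # one uniform per raw feature per sample, counter-seeded
  n_feat <- length(roles$idx_num) + length(roles$idx_bin) + length(roles$blocks)
  U <- matrix(0, n_samples, n_feat)
  for (i in seq_len(n_samples)) {
    set.seed(sample_seed(seed, i, salt = 1L))
    U[i, ] <- stats::runif(n_feat)
  }
  X <- P
  pos <- 0L
  if (length(roles$idx_num)) {
    eps <- stats::qnorm(U[, seq_along(roles$idx_num), drop = FALSE])
    X[, roles$idx_num] <- pmin(pmax(
      P[, roles$idx_num, drop = FALSE] +
        sweep(eps, 2L, exp(fit$log_sigma), "*"), 0), 1)
    pos <- length(roles$idx_num)
  }
  if (length(roles$idx_bin)) {
    ub <- U[, pos + seq_along(roles$idx_bin), drop = FALSE]
    X[, roles$idx_bin] <- (ub < P[, roles$idx_bin, drop = FALSE]) * 1
    pos <- pos + length(roles$idx_bin)
  }
  for (j in seq_along(roles$blocks)) {
    blk <- roles$blocks[[j]]
    cum <- t(apply(P[, blk, drop = FALSE], 1L, cumsum))
    pick <- pmin(rowSums(U[, pos + j] > cum) + 1L, length(blk))
    oh <- matrix(0, n_samples, length(blk))
    oh[cbind(seq_len(n_samples), pick)] <- 1
    X[, blk] <- oh
  }
  inverse_transform(template, X)
}
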