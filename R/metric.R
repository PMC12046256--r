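#' Learned Riemannian metric over the latent space
#'
#' The latent metric is parameterized by centroids \eqn{c_i} and
#' lower-triangular factors \eqn{L_i}:
#' \deqn{G^{-1}(z) = \sum_i L_i L_i^\top \exp(-\|z - c_i\|^2 / T^2) + \lambda I}
#' so the *inverse* metric is a centroid-weighted sum of positive
#' semi-definite blocks with a regularization floor \eqn{\lambda I} that
#' guarantees positive definiteness everywhere and makes
#' \eqn{G^{-1}(z) \to \lambda I} far from the data. Large \eqn{G^{-1}} (small
#' distances) marks the region of latent space the model actually supports;
#' samplers exploit this through the volume element.
#'
#' @param centroids K x d_z matrix of latent centroid locations.
#' @param factors Either a K x d_z matrix (interpreted as the diagonals of
#'   diagonal factors — the form the training loop learns) or a
#'   K x d_z x d_z array of lower-triangular matrices.
#' @param temperature Kernel bandwidth T > 0.
#' @param lambda Regularization floor λ > 0.
#' @return A `riemannian_metric` object.
#' @export
riemannian_metric <- function(centroids, factors, temperature = 0.8,
                              lambda = 1e-3) {
  centroids <- as.matrix(centroids)
  stopifnot(temperature > 0, lambda > 0)
  K <- nrow(centroids); dz <- ncol(centroids)
  if (is.matrix(factors)) {
    stopifnot(nrow(factors) == K, ncol(factors) == dz)
    m <- list(centroids = centroids, diag = TRUE,
              Mdiag = factors^2,                 # M_i = L_i L_i' for diagonal L_i
              factors = factors,
              temperature = temperature, lambda = lambda)
  } else {
    stopifnot(length(dim(factors)) == 3L, dim(factors)[1L] == K,
              dim(factors)[2L] == dz, dim(factors)[3L] == dz)
    Mflat <- matrix(0, K, dz * dz)
    for (i in seq_len(K)) {
      L <- factors[i, , ]
      L[upper.tri(L)] <- 0                       # enforce lower-triangular
      Mflat[i, ] <- as.vector(L %*% t(L))
    }
    m <- list(centroids = centroids, diag = FALSE, Mflat = Mflat,
              factors = factors, temperature = temperature, lambda = lambda)
  }
  structure(m, class = "riemannian_metric")
}

#' @export
print.riemannian_metric <- function(x, ...) {
  cat("<riemannian_metric> ", nrow(x$centroids), " centroids in ",
      ncol(x$centroids), "-d latent space (T = ", x$temperature,
      ", lambda = ", x$lambda,
      if (x$diag) ", diagonal factors" else ", triangular factors",
      ")\n", sep = "")
  invisible(x)
}

# Gaussian kernel weights exp(-||z - c_i||^2 / T^2) for rows of Z: n x K
metric_kernel <- function(metric, Z) {
  C <- metric$centroids
  d2 <- outer(rowSums(Z^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(Z)), rowSums(C^2)) - 2 * Z %*% t(C)
  exp(-pmax(d2, 0) / metric$temperature^2)
}

#' Evaluate the inverse metric tensor at a latent point
#'
#' @param metric A [riemannian_metric()].
#' @param z Latent point (numeric vector of length d_z).
#' @return The d_z x d_z symmetric positive-definite matrix G^{-1}(z).
#' @examples
#' m <- riemannian_metric(matrix(0, 1, 2), matrix(1, 1, 2), 1, 0.001)
#' metric_inverse(m, c(0, 0)) # 1.001 * I
#' @export
metric_inverse <- function(metric, z) {
  stopifnot(inherits(metric, "riemannian_metric"))
  dz <- ncol(metric$centroids)
  stopifnot(length(z) == dz)
  k <- drop(metric_kernel(metric, matrix(z, 1L)))
  if (metric$diag) {
    diag(drop(crossprod(k, metric$Mdiag)) + metric$lambda, dz)
  } else {
    matrix(drop(crossprod(k, metric$Mflat)), dz, dz) + metric$lambda * diag(dz)
  }
}

# 0.5 * log det G^{-1}(z) for each row of Z (the log volume element of the
# sampler's target, up to sign). Vectorized for the diagonal case.
metric_log_volume <- function(metric, Z) {
  Z <- as.matrix(Z)
  K <- metric_kernel(metric, Z)
  if (metric$diag) {
    Ginv <- K %*% metric$Mdiag + metric$lambda
    0.5 * rowSums(log(Ginv))
  } else {
    dz <- ncol(metric$centroids)
    apply(K, 1L, function(k) {
      Ginv <- matrix(drop(crossprod(k, metric$Mflat)), dz, dz) +
        metric$lambda * diag(dz)
      sum(log(diag(chol(Ginv))))
    })
  }
}

# gradient of the Hamiltonian H(z, p) = U(z) + 0.5 p' Ginv(z) p
#                                     - 0.5 log det Ginv(z)
# w.r.t. z (excluding the U term), at a single (z, p). Generic path.
metric_grad_z_kinetic <- function(metric, z, p) {
  dz <- length(z)
  k <- drop(metric_kernel(metric, matrix(z, 1L)))
  diff <- sweep(metric$centroids, 2L, z, "-")       # K x dz, c_i - z
  if (metric$diag) {
    pMp <- drop(metric$Mdiag %*% p^2)               # p' M_i p
    Ginv <- drop(crossprod(k, metric$Mdiag)) + metric$lambda
    trGM <- drop(metric$Mdiag %*% (1 / Ginv))       # tr(G M_i), G = Ginv^-1
  } else {
    P <- as.vector(outer(p, p))
    pMp <- drop(metric$Mflat %*% P)
    Ginv <- matrix(drop(crossprod(k, metric$Mflat)), dz, dz) +
      metric$lambda * diag(dz)
    Gfull <- chol2inv(chol(Ginv))
    trGM <- drop(metric$Mflat %*% as.vector(Gfull))
  }
  tt <- metric$temperature^2
  # kinetic: 0.5 p' dGinv p ; log-volume: -0.5 tr(G dGinv)
  drop(crossprod(k * (pMp - trGM), diff)) / tt
}

# grad_p H = Ginv(z) p
metric_grad_p <- function(metric, z, p) {
  drop(metric_inverse(metric, z) %*% p)
}
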