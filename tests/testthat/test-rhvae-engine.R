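blob_encoded <- function(n = 200, seed = 17) {
  # 2-d correlated Gaussian blob wrapped in a two-numeric schema
  set.seed(seed)
  u <- rnorm(n)
  sch <- cohort_schema(col_numeric("x", -10, 10), col_numeric("y", -10, 10))
  tab <- validate_cohort(
    data.frame(x = u + 0.3 * rnorm(n), y = 0.8 * u + 0.3 * rnorm(n)), sch)
  fit_transform(tab, sch)
}

test_that("training is seed-reproducible and logs every epoch", {
  enc <- blob_encoded()
  cfg <- rhvae_config(latent_dim = 2, hidden = c(8, 4), epochs = 5,
                      batch_size = 32, seed = 4)
  f1 <- rhvae(enc, cfg)
  f2 <- rhvae(enc, cfg)
  expect_identical(f1$training_log, f2$training_log)
  expect_identical(nrow(f1$training_log), 5L)
  f3 <- rhvae(enc, rhvae_config(latent_dim = 2, hidden = c(8, 4), epochs = 5,
                                batch_size = 32, seed = 5))
  expect_false(identical(f1$training_log$loss, f3$training_log$loss))
})

test_that("batch sizes larger than the cohort are rejected", {
  enc <- blob_encoded(n = 20)
  expect_error(rhvae(enc, rhvae_config(batch_size = 64)), "exceeds")
})

test_that("the model beats the mean predictor on a Gaussian blob", {
  enc <- blob_encoded()
  fit <- rhvae(enc, rhvae_config(latent_dim = 2, hidden = c(16, 8),
                                 epochs = 200, batch_size = 32, seed = 6))
  ef <- synthcohort:::encoder_forward(fit$encoder, enc$values)
  P <- synthcohort:::decoder_probs(
    synthcohort:::decoder_forward(fit$decoder, ef$mu)$A, fit$roles)
  mse_model <- mean((P - enc$values)^2)
  mse_mean <- mean(sweep(enc$values, 2, colMeans(enc$values))^2)
  expect_lt(mse_model, mse_mean)
  # loss falls substantially over training
  expect_lt(utils::tail(fit$training_log$loss, 1), fit$training_log$loss[1])
})

test_that("analytic gradients match finite differences on a tiny model", {
  set.seed(42)
  sch <- cohort_schema(col_numeric("a", 0, 1), col_numeric("b", 0, 1),
                       col_binary("c"), col_categorical("d", c("x", "y", "z")))
  # include boundary values so the censored-likelihood branches are exercised
  tab <- validate_cohort(
    data.frame(a = c(0, 0.31, 1, 0.72, 0.05, 0.9),
               b = c(0.5, 0, 1, 1, 0.2, 0.44),
               c = sample(c("0", "1"), 6, TRUE),
               d = sample(c("x", "y", "z"), 6, TRUE)), sch)
  enc <- fit_transform(tab, sch)
  fit <- rhvae(enc, rhvae_config(latent_dim = 2, hidden = c(4, 3), epochs = 1,
                                 batch_size = 6, n_leapfrog_steps = 0, seed = 3))
  X <- enc$values
  eps <- matrix(rnorm(12), 6, 2)
  loss_of <- function(f) rhvae_objective(f, X, eps)$loss

  ef <- synthcohort:::encoder_forward(fit$encoder, X)
  sd_z <- exp(0.5 * ef$lv)
  Z <- ef$mu + sd_z * eps
  df <- synthcohort:::decoder_forward(fit$decoder, Z)
  rec <- synthcohort:::recon_nll(df$A, X, fit$roles, fit$log_sigma, grad = TRUE)
  B <- 6
  dA <- rec$dA / B
  dbwd <- synthcohort:::nn_trunk_backward(fit$decoder$trunk, df$acts,
                                          dA %*% t(fit$decoder$W_out))
  dZ <- dbwd$dX
  dmu <- dZ + ef$mu / B
  dlv <- (dZ * 0.5 * sd_z * eps + 0.5 * (exp(ef$lv) - 1) / B) * ef$lv_mask
  H <- ef$acts[[length(ef$acts)]]
  ebwd <- synthcohort:::nn_trunk_backward(
    fit$encoder$trunk, ef$acts,
    dmu %*% t(fit$encoder$W_mu) + dlv %*% t(fit$encoder$W_lv))

  h <- 1e-6
  fd_check <- function(analytic, bump) {
    num <- vapply(seq_along(analytic), function(i) {
      (loss_of(bump(i, h)) - loss_of(bump(i, -h))) / (2 * h)
    }, numeric(1))
    expect_equal(num, as.numeric(analytic), tolerance = 1e-5)
  }
  fd_check(ebwd$grads[[1]]$W,
           function(i, d) { f <- fit; f$encoder$trunk[[1]]$W[i] <- f$encoder$trunk[[1]]$W[i] + d; f })
  fd_check(crossprod(H, dmu),
           function(i, d) { f <- fit; f$encoder$W_mu[i] <- f$encoder$W_mu[i] + d; f })
  fd_check(crossprod(H, dlv),
           function(i, d) { f <- fit; f$encoder$W_lv[i] <- f$encoder$W_lv[i] + d; f })
  fd_check(dbwd$grads[[1]]$W,
           function(i, d) { f <- fit; f$decoder$trunk[[1]]$W[i] <- f$decoder$trunk[[1]]$W[i] + d; f })
  fd_check(crossprod(df$acts[[length(df$acts)]], dA),
           function(i, d) { f <- fit; f$decoder$W_out[i] <- f$decoder$W_out[i] + d; f })
  fd_check(rec$dlog_sigma / B,
           function(i, d) { f <- fit; f$log_sigma[i] <- f$log_sigma[i] + d; f })
})

test_that("with identity metric and no leapfrog steps the engine is a vanilla VAE", {
  # independent straightforward ELBO implementation, written against the
  # stored weights only
  enc <- blob_encoded(n = 64)
  fit <- rhvae(enc, rhvae_config(latent_dim = 2, hidden = c(6, 4), epochs = 3,
                                 batch_size = 32, n_leapfrog_steps = 0, seed = 9))
  X <- enc$values[1:32, ]
  set.seed(10)
  eps <- matrix(rnorm(64), 32, 2)

  obj <- rhvae_objective(fit, X, eps)
  expect_equal(obj$loss, oracle_elbo(fit, X, eps), tolerance = 1e-5)
})

test_that("batched Hamiltonian refinement agrees with the generic integrator", {
  fit <- small_fit()
  metric <- fit$metric
  enc <- fit_transform(simulate_cohort(fixture_config(n_patients = 4, seed = 30)),
                       fixture_schema())
  X <- enc$values[1:2, , drop = FALSE]
  set.seed(55)
  Z0 <- matrix(rnorm(2 * fit$config$latent_dim, sd = 0.5), 2)
  # reproduce the refinement's internal momentum draw
  set.seed(56)
  km <- synthcohort:::batch_metric_ginv(metric, Z0)
  P0 <- matrix(rnorm(length(Z0)), 2) / sqrt(km$Ginv)
  set.seed(56)
  Zb <- synthcohort:::refine_latent_batch(fit$decoder, fit$log_sigma, fit$roles,
                                          X, Z0, metric, steps = 3,
                                          step_size = 0.01)
  for (i in 1:2) {
    gU <- function(z) {
      drop(synthcohort:::grad_potential_batch(
        fit$decoder, fit$log_sigma, fit$roles,
        X[i, , drop = FALSE], matrix(z, 1)))
    }
    out <- leapfrog_integrate(metric, Z0[i, ], P0[i, ], gU,
                              steps = 3, step_size = 0.01)
    expect_equal(Zb[i, ], out$z, tolerance = 1e-7)
  }
})
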