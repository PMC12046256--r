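# Shared fixtures for the test suite. Heavy objects are built once per run,
# lazily, and cached in this environment.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

# a small mixed-type schema exercised by most preprocessing tests
toy_schema <- function() {
  cohort_schema(
    col_numeric("age", 18, 95, integer_valued = TRUE),
    col_numeric("score", 0, 100),
    col_binary("flag", c("no", "yes")),
    col_categorical("grade", c("A", "B", "C"))
  )
}

toy_table <- function(n = 20, seed = 42) {
  set.seed(seed)
  validate_cohort(
    data.frame(
      age = sample(18:95, n, replace = TRUE),
      score = round(runif(n, 0, 100), 3),
      flag = sample(c("no", "yes"), n, replace = TRUE),
      grade = sample(c("A", "B", "C"), n, replace = TRUE)
    ),
    toy_schema()
  )
}

# the default-condition fixture cohort (521 patients)
fixture_cohort <- function() {
  cached("fixture_cohort", simulate_cohort(fixture_config(seed = 1)))
}

fixture_encoded <- function() {
  cached("fixture_encoded", fit_transform(fixture_cohort(), fixture_schema()))
}

# a reduced-size trained model shared by engine/generator unit tests
small_fit <- function() {
  cached("small_fit", {
    cfg <- fixture_config(n_patients = 200, seed = 5)
    enc <- fit_transform(simulate_cohort(cfg), fixture_schema())
    rhvae(enc, rhvae_config(epochs = 40, seed = 3))
  })
}

# a random valid metric with full lower-triangular factors
random_metric <- function(K = 5, dz = 3, seed = 1, diag = FALSE,
                          temperature = 1, lambda = 1e-3) {
  set.seed(seed)
  C <- matrix(rnorm(K * dz), K, dz)
  if (diag) {
    riemannian_metric(C, matrix(runif(K * dz, 0.3, 2), K, dz),
                      temperature, lambda)
  } else {
    L <- array(0, c(K, dz, dz))
    for (i in seq_len(K)) {
      Li <- matrix(rnorm(dz * dz, sd = 0.7), dz, dz)
      Li[upper.tri(Li)] <- 0
      diag(Li) <- abs(diag(Li)) + 0.2
      L[i, , ] <- Li
    }
    riemannian_metric(C, L, temperature, lambda)
  }
}

# the scaled-down end-to-end study reproduction shared by the acceptance
# tests: train on the default fixture (300 epochs), generate 5000 artificial
# patients with the metric-walk sampler, audit both ways
e2e_run <- function() {
  cached("e2e_run", {
    enc <- fixture_encoded()
    fit <- rhvae(enc, rhvae_config(epochs = 300, seed = 7))
    art <- generate_cohort(fit, 5000, seed = 11, sampler = "metric-walk")
    list(fit = fit, artificial = art,
         report = audit_cohorts(fixture_cohort(), art, fixture_schema(),
                                encoded = enc))
  })
}

# independent straightforward ELBO implementation (vanilla VAE with the
# censored-Gaussian/Bernoulli/categorical likelihood), written directly
# against the stored weights; the oracle for the vanilla-reduction check
oracle_elbo <- function(fit, X, eps) {
  act <- X
  for (l in fit$encoder$trunk) act <- tanh(sweep(act %*% l$W, 2, l$b, "+"))
  mu <- sweep(act %*% fit$encoder$W_mu, 2, fit$encoder$b_mu, "+")
  lv <- pmin(pmax(sweep(act %*% fit$encoder$W_lv, 2, fit$encoder$b_lv, "+"), -8), 8)
  z <- mu + exp(lv / 2) * eps
  a <- z
  for (l in fit$decoder$trunk) a <- tanh(sweep(a %*% l$W, 2, l$b, "+"))
  a <- sweep(a %*% fit$decoder$W_out, 2, fit$decoder$b_out, "+")
  roles <- fit$roles
  nll <- 0
  if (length(roles$idx_num)) {
    s <- exp(fit$log_sigma)
    for (jj in seq_along(roles$idx_num)) {
      j <- roles$idx_num[jj]
      x <- X[, j]
      m <- 1 / (1 + exp(-a[, j]))
      inner <- x > 0 & x < 1
      nll <- nll + sum(log(s[jj]) + 0.5 * log(2 * pi) +
                         0.5 * ((x[inner] - m[inner]) / s[jj])^2) -
        sum(pnorm(-m[x <= 0] / s[jj], log.p = TRUE)) -
        sum(pnorm((m[x >= 1] - 1) / s[jj], log.p = TRUE))
    }
  }
  for (j in roles$idx_bin) {
    p <- 1 / (1 + exp(-a[, j]))
    nll <- nll - sum(X[, j] * log(p) + (1 - X[, j]) * log(1 - p))
  }
  for (blk in roles$blocks) {
    sm <- exp(a[, blk])
    sm <- sm / rowSums(sm)
    nll <- nll - sum(X[, blk] * log(sm))
  }
  kl <- 0.5 * sum(mu^2 + exp(lv) - 1 - lv)
  (nll + kl) / nrow(X)
}
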