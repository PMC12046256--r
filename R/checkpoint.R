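#' Save / load a trained model checkpoint
#'
#' A checkpoint is a single JSON file holding the encoder/decoder weights,
#' the learned metric, the training configuration and log, and the decoding
#' sidecar (column map, scaler state, schema) needed to turn generated
#' vectors back into patient records. Full double precision is preserved.
#'
#' @param fit An `rhvae_fit`.
#' @param path Checkpoint file path (conventionally `.json`).
#' @return `save_rhvae()` returns `path` invisibly; `read_rhvae()` returns an
#'   `rhvae_fit` equivalent to the saved one.
#' @export
save_rhvae <- function(fit, path) {
  stopifnot(inherits(fit, "rhvae_fit"))
  ser_trunk <- function(trunk) purrr::map(trunk, function(l) list(W = l$W, b = l$b))
  obj <- list(
    format = "synthcohort-rhvae",
    version = as.character(utils::packageVersion("synthcohort")),
    config = unclass(fit$config),
    encoder = list(trunk = ser_trunk(fit$encoder$trunk),
                   W_mu = fit$encoder$W_mu, b_mu = fit$encoder$b_mu,
                   W_lv = fit$encoder$W_lv, b_lv = fit$encoder$b_lv),
    decoder = list(trunk = ser_trunk(fit$decoder$trunk),
                   W_out = fit$decoder$W_out, b_out = fit$decoder$b_out),
    log_sigma = fit$log_sigma,
    metric = list(centroids = fit$metric$centroids,
                  factors = fit$metric$factors,
                  diag = fit$metric$diag,
                  temperature = fit$metric$temperature,
                  lambda = fit$metric$lambda),
    training_log = fit$training_log,
    column_map = fit$sidecar$column_map,
    scaler_state = fit$sidecar$scaler_state,
    schema = schema_to_list(fit$sidecar$schema),
    n_train = fit$n_train
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname save_rhvae
#' @export
read_rhvae <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "synthcohort-rhvae")) {
    stop("'", path, "' is not a synthcohort model checkpoint", call. = FALSE)
  }
  # simplifyVector may turn the list of layers into a data frame of lists
  de_trunk <- function(trunk) {
    if (is.data.frame(trunk)) {
      purrr::map(seq_len(nrow(trunk)), function(i) {
        list(W = as.matrix(trunk$W[[i]]), b = as.numeric(trunk$b[[i]]))
      })
    } else {
      purrr::map(trunk, function(l) list(W = as.matrix(l$W), b = as.numeric(l$b)))
    }
  }
  cfg <- obj$config
  config <- rhvae_config(
    latent_dim = cfg$latent_dim, hidden = cfg$hidden, epochs = cfg$epochs,
    batch_size = cfg$batch_size, learning_rate = cfg$learning_rate,
    n_leapfrog_steps = cfg$n_leapfrog_steps,
    leapfrog_step_size = cfg$leapfrog_step_size,
    metric_temperature = cfg$metric_temperature,
    metric_regularization = cfg$metric_regularization,
    n_metric_centroids = if (length(cfg$n_metric_centroids)) cfg$n_metric_centroids else NULL,
    kl_warmup_epochs = cfg$kl_warmup_epochs %||% 0,
    seed = cfg$seed
  )
  schema <- schema_from_list(
    jsonlite::read_json(path)$schema
  )
  metric <- riemannian_metric(
    as.matrix(obj$metric$centroids),
    if (isTRUE(obj$metric$diag)) as.matrix(obj$metric$factors) else obj$metric$factors,
    temperature = obj$metric$temperature, lambda = obj$metric$lambda
  )
  column_map <- tibble::as_tibble(obj$column_map)
  structure(
    list(
      encoder = list(trunk = de_trunk(obj$encoder$trunk),
                     W_mu = as.matrix(obj$encoder$W_mu),
                     b_mu = as.numeric(obj$encoder$b_mu),
                     W_lv = as.matrix(obj$encoder$W_lv),
                     b_lv = as.numeric(obj$encoder$b_lv)),
      decoder = list(trunk = de_trunk(obj$decoder$trunk),
                     W_out = as.matrix(obj$decoder$W_out),
                     b_out = as.numeric(obj$decoder$b_out)),
      log_sigma = as.numeric(obj$log_sigma),
      metric = metric,
      roles = encoded_roles(column_map),
      config = config,
      training_log = tibble::as_tibble(obj$training_log),
      sidecar = list(column_map = column_map,
                     scaler_state = tibble::as_tibble(obj$scaler_state),
                     schema = schema),
      n_train = obj$n_train
    ),
    class = "rhvae_fit"
  )
}
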