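#' Encode a validated cohort as a numeric design matrix
#'
#' The tabular processor turns a mixed-type patient table into a fully numeric
#' matrix the generative model can train on: numerical columns are min-max
#' scaled to [0, 1] using the range observed in `data`, binary columns map to
#' a single 0/1 column by level order, and categorical columns expand to
#' one-hot indicator blocks. The returned object carries full column
#' provenance and the scaler state needed to invert the mapping.
#'
#' @param data A schema-conforming tibble (see [validate_cohort()]).
#' @param schema A [cohort_schema()].
#' @return An `encoded_cohort` with elements:
#'   \describe{
#'     \item{values}{n x d numeric matrix, all entries in [0, 1].}
#'     \item{column_map}{tibble: encoded column, source column, role
#'       (`scaled-numeric`, `binary`, `one-hot`), level (one-hot only).}
#'     \item{scaler_state}{tibble of per-numeric (min, max) used for scaling,
#'       with a `degenerate` flag where min == max (such columns encode as
#'       constant 0).}
#'     \item{schema}{the schema, kept for decoding.}
#'   }
#' @examples
#' sch <- cohort_schema(col_numeric("age", 0, 100), col_binary("sex", c("F", "M")))
#' tab <- validate_cohort(data.frame(age = c(0, 50, 100), sex = c("F", "M", "F")), sch)
#' fit_transform(tab, sch)$values
#' @export
fit_transform <- function(data, schema) {
  stopifnot(inherits(schema, "cohort_schema"))
  data <- validate_cohort(data, schema)
  if (nrow(data) == 0L) stop("cannot fit the processor on an empty table", call. = FALSE)
  n <- nrow(data)
  blocks <- vector("list", nrow(schema))
  maps <- vector("list", nrow(schema))
  scalers <- list()
  for (i in seq_len(nrow(schema))) {
    spec <- schema[i, ]
    v <- data[[spec$name]]
    if (spec$kind == "numerical") {
      lo <- min(v); hi <- max(v)
      degenerate <- hi <= lo
      scaled <- if (degenerate) {
        warning("numeric column '", spec$name,
                "' is constant; encoded as 0", call. = FALSE)
        rep(0, n)
      } else {
        (v - lo) / (hi - lo)
      }
      blocks[[i]] <- matrix(scaled, ncol = 1L)
      maps[[i]] <- tibble::tibble(encoded = spec$name, source = spec$name,
                                  role = "scaled-numeric", level = NA_character_)
      scalers[[length(scalers) + 1L]] <- tibble::tibble(
        column = spec$name, min = lo, max = hi, degenerate = degenerate
      )
    } else if (spec$kind == "binary") {
      lev <- spec$levels[[1L]]
      blocks[[i]] <- matrix(as.numeric(v == lev[2L]), ncol = 1L)
      maps[[i]] <- tibble::tibble(encoded = spec$name, source = spec$name,
                                  role = "binary", level = NA_character_)
    } else {
      lev <- spec$levels[[1L]]
      oh <- matrix(0, n, length(lev))
      oh[cbind(seq_len(n), match(as.character(v), lev))] <- 1
      blocks[[i]] <- oh
      maps[[i]] <- tibble::tibble(
        encoded = paste(spec$name, lev, sep = "."),
        source = spec$name, role = "one-hot", level = lev
      )
    }
  }
  values <- do.call(cbind, blocks)
  column_map <- dplyr::bind_rows(maps)
  colnames(values) <- column_map$encoded
  structure(
    list(values = values, column_map = column_map,
         scaler_state = dplyr::bind_rows(scalers), schema = schema),
    class = "encoded_cohort"
  )
}

#' @export
print.encoded_cohort <- function(x, ...) {
  cat("<encoded_cohort> ", nrow(x$values), " x ", ncol(x$values),
      " design matrix (", sum(x$column_map$role == "scaled-numeric"),
      " scaled numerics, ", sum(x$column_map$role == "binary"), " binaries, ",
      sum(x$column_map$role == "one-hot"), " one-hot indicators)\n", sep = "")
  invisible(x)
}

#' Encode new data with an already-fitted processor
#'
#' Applies the scaling/one-hot mapping learned by [fit_transform()] to another
#' schema-conforming table (e.g. an artificial cohort encoded with the real
#' cohort's scaler state, as nearest-neighbour privacy audits require).
#'
#' @param encoded An `encoded_cohort` from [fit_transform()].
#' @param data A schema-conforming table.
#' @return n x d numeric matrix. Numerics scaled with the *stored* min/max are
#'   not re-clipped, so values outside the training range fall outside [0, 1].
#' @export
apply_transform <- function(encoded, data) {
  stopifnot(inherits(encoded, "encoded_cohort"))
  schema <- encoded$schema
  data <- validate_cohort(data, schema)
  n <- nrow(data)
  blocks <- vector("list", nrow(schema))
  for (i in seq_len(nrow(schema))) {
    spec <- schema[i, ]
    v <- data[[spec$name]]
    if (spec$kind == "numerical") {
      sc <- encoded$scaler_state[encoded$scaler_state$column == spec$name, ]
      blocks[[i]] <- matrix(
        if (sc$degenerate) rep(0, n) else (v - sc$min) / (sc$max - sc$min),
        ncol = 1L
      )
    } else if (spec$kind == "binary") {
      blocks[[i]] <- matrix(as.numeric(v == spec$levels[[1L]][2L]), ncol = 1L)
    } else {
      lev <- spec$levels[[1L]]
      oh <- matrix(0, n, length(lev))
      oh[cbind(seq_len(n), match(as.character(v), lev))] <- 1
      blocks[[i]] <- oh
    }
  }
  values <- do.call(cbind, blocks)
  colnames(values) <- encoded$column_map$encoded
  values
}

#' Decode a numeric matrix back into a patient table
#'
#' Inverts [fit_transform()]: scaled numerics are unscaled with the stored
#' (min, max), clipped to the schema range, and rounded half away from zero
#' when integer-valued; binary columns threshold at 0.5; one-hot blocks decode
#' by argmax (ties break toward the lowest-index level). The result validates
#' against the schema.
#'
#' @param encoded An `encoded_cohort` (the template holding column map, scaler
#'   state and schema).
#' @param values Numeric matrix with `ncol(values)` equal to the encoded
#'   width; defaults to the template's own matrix (round trip).
#' @return A schema-conforming tibble with `nrow(values)` patients.
#' @examples
#' sch <- cohort_schema(col_numeric("age", 0, 100), col_binary("sex", c("F", "M")))
#' tab <- validate_cohort(data.frame(age = c(0, 50, 100), sex = c("F", "M", "F")), sch)
#' enc <- fit_transform(tab, sch)
#' identical(inverse_transform(enc), tab)
#' @export
inverse_transform <- function(encoded, values = encoded$values) {
  stopifnot(inherits(encoded, "encoded_cohort"))
  values <- as.matrix(values)
  d <- nrow(encoded$column_map)
  if (ncol(values) != d) {
    stop("matrix has ", ncol(values), " columns; template encodes ", d, call. = FALSE)
  }
  schema <- encoded$schema
  n <- nrow(values)
  out <- vector("list", nrow(schema))
  pos <- 1L
  for (i in seq_len(nrow(schema))) {
    spec <- schema[i, ]
    if (spec$kind == "numerical") {
      sc <- encoded$scaler_state[encoded$scaler_state$column == spec$name, ]
      x <- if (sc$degenerate) rep(sc$min, n) else sc$min + values[, pos] * (sc$max - sc$min)
      x <- pmin(pmax(x, spec$min), spec$max)
      if (spec$integer_valued) x <- round_half_away(x)
      out[[i]] <- x
      pos <- pos + 1L
    } else if (spec$kind == "binary") {
      lev <- spec$levels[[1L]]
      out[[i]] <- factor(lev[1L + (values[, pos] >= 0.5)], levels = lev)
      pos <- pos + 1L
    } else {
      lev <- spec$levels[[1L]]
      block <- values[, pos:(pos + length(lev) - 1L), drop = FALSE]
      out[[i]] <- factor(lev[max.col(block, ties.method = "first")], levels = lev)
      pos <- pos + length(lev)
    }
  }
  names(out) <- schema$name
  res <- tibble::as_tibble(out)
  validate_cohort(res, schema)
}

#' Persist / restore an encoded design matrix
#'
#' Writes the numeric design matrix as CSV and its provenance (column map,
#' scaler state, schema) as a JSON sidecar next to it, so an encoding can be
#' inspected with ordinary tools and restored losslessly.
#'
#' @param encoded An `encoded_cohort` from [fit_transform()].
#' @param path CSV file path; the sidecar is written at `<path>.json`.
#' @return `write_encoded()` returns `path` invisibly; `read_encoded()`
#'   returns an `encoded_cohort`.
#' @export
write_encoded <- function(encoded, path) {
  stopifnot(inherits(encoded, "encoded_cohort"))
  utils::write.csv(as.data.frame(encoded$values), path, row.names = FALSE)
  jsonlite::write_json(
    list(column_map = encoded$column_map,
         scaler_state = encoded$scaler_state,
         schema = schema_to_list(encoded$schema)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_encoded
#' @export
read_encoded <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  values <- as.matrix(utils::read.csv(path, check.names = FALSE))
  structure(
    list(values = values,
         column_map = tibble::as_tibble(sidecar$column_map),
         scaler_state = tibble::as_tibble(sidecar$scaler_state),
         schema = schema_from_list(jsonlite::read_json(paste0(path, ".json"))$schema)),
    class = "encoded_cohort"
  )
}
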