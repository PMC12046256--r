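#' Column specifications for a clinical cohort schema
#'
#' A cohort schema describes every column of a patient-level table: its name,
#' kind (`"numerical"`, `"binary"` or `"categorical"`), the admissible levels
#' for discrete columns, and the admissible range for numerical columns.
#' Schemas drive validation, encoding to a numeric design matrix, and decoding
#' of generated vectors back into valid patient records.
#'
#' @param name Column name (single string).
#' @param min,max Admissible range for a numerical column (`min < max`; equal
#'   bounds are accepted but flagged degenerate at encoding time).
#' @param integer_valued Should decoded values be rounded to whole numbers
#'   (half away from zero)? E.g. age in years.
#' @param levels Ordered character vector of levels: exactly 2 for binary
#'   columns (the second level encodes as 1), at least 3 for categorical.
#'
#' @return A one-row tibble (a column spec) that [cohort_schema()] accepts.
#' @examples
#' col_numeric("age", 18, 95, integer_valued = TRUE)
#' col_binary("diabetes", c("no", "yes"))
#' col_categorical("met", c("lt4", "4to6", "6to10", "gt10"))
#' @name column-specs
NULL

#' @rdname column-specs
#' @export
col_numeric <- function(name, min, max, integer_valued = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.numeric(min), is.numeric(max), length(min) == 1L, length(max) == 1L)
  if (min > max) stop("numerical column '", name, "': min > max", call. = FALSE)
  tibble::tibble(
    name = name, kind = "numerical", levels = list(NULL),
    min = as.numeric(min), max = as.numeric(max),
    integer_valued = isTRUE(integer_valued)
  )
}

#' @rdname column-specs
#' @export
col_binary <- function(name, levels = c("0", "1")) {
  stopifnot(is.character(name), length(name) == 1L)
  levels <- as.character(levels)
  if (length(levels) != 2L || anyDuplicated(levels)) {
    stop("binary column '", name, "' needs exactly 2 distinct levels", call. = FALSE)
  }
  tibble::tibble(
    name = name, kind = "binary", levels = list(levels),
    min = NA_real_, max = NA_real_, integer_valued = FALSE
  )
}

#' @rdname column-specs
#' @export
col_categorical <- function(name, levels) {
  stopifnot(is.character(name), length(name) == 1L)
  levels <- as.character(levels)
  if (length(levels) < 3L || anyDuplicated(levels)) {
    stop("categorical column '", name, "' needs >= 3 distinct levels ",
         "(use col_binary for 2)", call. = FALSE)
  }
  tibble::tibble(
    name = name, kind = "categorical", levels = list(levels),
    min = NA_real_, max = NA_real_, integer_valued = FALSE
  )
}

#' Assemble a cohort schema
#'
#' @param ... Column specs created by [col_numeric()], [col_binary()],
#'   [col_categorical()], or tibbles of such rows.
#' @return A `cohort_schema`: a tibble with one row per column and class
#'   `"cohort_schema"`, carrying `n_raw_features` and the encoded design-matrix
#'   width as attributes (also available via [encoded_width()]).
#' @examples
#' sch <- cohort_schema(
#'   col_numeric("age", 18, 95, TRUE),
#'   col_binary("smoker", c("no", "yes")),
#'   col_categorical("asa", c("I", "II", "III", "IV"))
#' )
#' encoded_width(sch) # 1 + 1 + 4
#' @export
cohort_schema <- function(...) {
  cols <- dplyr::bind_rows(...)
  if (nrow(cols) == 0L) stop("a schema needs at least one column", call. = FALSE)
  if (anyDuplicated(cols$name)) {
    stop("duplicate column names in schema: ",
         paste(unique(cols$name[duplicated(cols$name)]), collapse = ", "),
         call. = FALSE)
  }
  structure(cols,
    class = c("cohort_schema", class(tibble::tibble())),
    n_raw_features = nrow(cols)
  )
}

#' Width of the encoded design matrix implied by a schema
#'
#' Numerical and binary columns contribute one encoded column each; a
#' categorical column contributes one indicator column per level.
#'
#' @param schema A [cohort_schema()].
#' @return Integer encoded width.
#' @export
encoded_width <- function(schema) {
  stopifnot(inherits(schema, "cohort_schema"))
  sum(ifelse(schema$kind == "categorical", lengths(schema$levels), 1L))
}

#' @export
print.cohort_schema <- function(x, ...) {
  cat("<cohort_schema> ", nrow(x), " features (",
      sum(x$kind == "numerical"), " numerical, ",
      sum(x$kind == "binary"), " binary, ",
      sum(x$kind == "categorical"), " categorical) -> encoded width ",
      encoded_width(x), "\n", sep = "")
  NextMethod()
}

#' Read / write a cohort schema as JSON
#'
#' The on-disk format is a JSON array of objects with fields `name`, `kind`,
#' and either `levels` (discrete columns) or `min`/`max`/`integer_valued`
#' (numerical columns).
#'
#' @param path File path.
#' @param schema A [cohort_schema()].
#' @return `read_schema()` returns a `cohort_schema`; `write_schema()` returns
#'   `path` invisibly.
#' @export
read_schema <- function(path) {
  schema_from_list(jsonlite::read_json(path))
}

schema_from_list <- function(raw) {
  specs <- purrr::map(raw, function(cs) {
    switch(cs$kind,
      numerical = col_numeric(cs$name, cs$min, cs$max, isTRUE(cs$integer_valued)),
      binary = col_binary(cs$name, unlist(cs$levels)),
      categorical = col_categorical(cs$name, unlist(cs$levels)),
      stop("unknown column kind: ", cs$kind, call. = FALSE)
    )
  })
  cohort_schema(dplyr::bind_rows(specs))
}

schema_to_list <- function(schema) {
  purrr::pmap(schema, function(name, kind, levels, min, max, integer_valued) {
    if (kind == "numerical") {
      list(name = name, kind = kind, min = min, max = max,
           integer_valued = integer_valued)
    } else {
      list(name = name, kind = kind, levels = as.list(levels))
    }
  })
}

#' @rdname read_schema
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "cohort_schema"))
  jsonlite::write_json(schema_to_list(schema), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Validate a raw table against a cohort schema
#'
#' Checks that every schema column is present, coerces values to their declared
#' kinds, imputes missing entries (numerical: column median; discrete: mode)
#' and rejects out-of-contract values. In strict mode any unparsable numeric or
#' unknown level is an error naming the offending row and column; otherwise
#' such cells are treated as missing and imputed.
#'
#' @param data A data frame with a column per schema entry (extra columns are
#'   an error; order is irrelevant).
#' @param schema A [cohort_schema()].
#' @param strict Reject unknown levels / unparsable numerics? Default `TRUE`.
#' @return A tibble with columns in schema order, values conforming to the
#'   schema and no missing entries. The per-column coercion/imputation log is
#'   attached as attribute `"coercion_log"` (a tibble: column, n_imputed,
#'   n_coerced).
#' @examples
#' sch <- cohort_schema(col_numeric("age", 18, 95), col_binary("sex", c("F", "M")))
#' validate_cohort(data.frame(age = c(30, NA), sex = c("F", "M")), sch)
#' @export
validate_cohort <- function(data, schema, strict = TRUE) {
  stopifnot(inherits(schema, "cohort_schema"), is.data.frame(data))
  unknown <- setdiff(names(data), schema$name)
  if (length(unknown)) {
    stop("columns not in schema: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(schema$name, names(data))
  if (length(missing_cols)) {
    stop("schema columns absent from data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(data)
  log <- vector("list", nrow(schema))
  out <- vector("list", nrow(schema))
  for (i in seq_len(nrow(schema))) {
    spec <- schema[i, ]
    v <- data[[spec$name]]
    if (spec$kind == "numerical") {
      suppressWarnings(num <- as.numeric(as.character(v)))
      bad <- !is.na(as.character(v)) & is.na(num)
      if (strict && any(bad)) {
        stop("unparsable numeric in column '", spec$name, "', row ",
             which(bad)[1L], call. = FALSE)
      }
      oob <- !is.na(num) & (num < spec$min | num > spec$max)
      if (strict && any(oob) && n > 0) {
        stop("value out of range [", spec$min, ", ", spec$max, "] in column '",
             spec$name, "', row ", which(oob)[1L], call. = FALSE)
      }
      num[oob] <- pmin(pmax(num[oob], spec$min), spec$max)
      n_imp <- sum(is.na(num))
      if (n_imp > 0) {
        if (n_imp == n) stop("column '", spec$name, "' is entirely missing", call. = FALSE)
        num[is.na(num)] <- stats::median(num, na.rm = TRUE)
      }
      if (spec$integer_valued) num <- round_half_away(num)
      out[[i]] <- num
      log[[i]] <- tibble::tibble(column = spec$name, n_imputed = n_imp,
                                 n_coerced = sum(bad) + sum(oob))
    } else {
      lev <- spec$levels[[1L]]
      ch <- as.character(v)
      bad <- !is.na(ch) & !(ch %in% lev)
      if (strict && any(bad)) {
        stop("level '", ch[which(bad)[1L]], "' not in {",
             paste(lev, collapse = ", "), "} in column '", spec$name,
             "', row ", which(bad)[1L], call. = FALSE)
      }
      ch[bad] <- NA_character_
      n_imp <- sum(is.na(ch))
      if (n_imp > 0) {
        if (n_imp == n) stop("column '", spec$name, "' is entirely missing", call. = FALSE)
        tab <- table(factor(ch, levels = lev))
        ch[is.na(ch)] <- names(tab)[which.max(tab)]
      }
      out[[i]] <- factor(ch, levels = lev)
      log[[i]] <- tibble::tibble(column = spec$name, n_imputed = n_imp,
                                 n_coerced = sum(bad))
    }
  }
  names(out) <- schema$name
  res <- tibble::as_tibble(out)
  attr(res, "coercion_log") <- dplyr::bind_rows(log)
  res
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
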