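#' Distribution and correlation stability between real and artificial cohorts
#'
#' The fidelity audit scores how well an artificial cohort preserves the
#' statistical structure of the real cohort it was generated from, on a 0-100
#' scale per component:
#' \describe{
#'   \item{numerical stability}{per numerical variable, a two-sample
#'     Kolmogorov-Smirnov test (asymptotic p-values, \eqn{\alpha} = 0.05, no
#'     multiplicity correction); the score is 100 times the fraction of
#'     variables whose distribution is *not* rejected.}
#'   \item{categorical stability}{per binary/categorical variable, 100 times
#'     one minus the total variation distance between the level-frequency
#'     vectors, averaged over variables.}
#'   \item{correlation stability}{100 times one minus the mean absolute
#'     off-diagonal difference between the Pearson correlation matrices of
#'     the numerical variables.}
#' }
#' The composite fidelity score is the arithmetic mean of the three
#' components.
#'
#' @param real,artificial Schema-conforming tibbles sharing `schema`.
#' @param schema A [cohort_schema()].
#' @param alpha Kolmogorov-Smirnov significance level (default 0.05).
#' @return `numerical_stability()` and `categorical_stability()` return a list
#'   with `score` (percent) and `detail` (per-variable tibble);
#'   `correlation_stability()` additionally returns `real`, `artificial` and
#'   `difference` correlation matrices.
#' @seealso [audit_fidelity()] for the one-call audit.
#' @name stability
NULL

#' @rdname stability
#' @export
numerical_stability <- function(real, artificial, schema, alpha = 0.05) {
  check_cohort_pair(real, artificial, schema)
  vars <- schema$name[schema$kind == "numerical"]
  if (!length(vars)) {
    warning("no numerical columns; numerical stability is undefined", call. = FALSE)
    return(list(score = NA_real_, detail = tibble::tibble()))
  }
  detail <- purrr::map_dfr(vars, function(v) {
    ks <- suppressWarnings(
      stats::ks.test(real[[v]], artificial[[v]], exact = FALSE)
    )
    tibble::tibble(variable = v, statistic = unname(ks$statistic),
                   p_value = ks$p.value, stable = ks$p.value >= alpha)
  })
  list(score = 100 * mean(detail$stable), detail = detail)
}

#' @rdname stability
#' @export
categorical_stability <- function(real, artificial, schema) {
  check_cohort_pair(real, artificial, schema)
  vars <- schema$name[schema$kind %in% c("binary", "categorical")]
  if (!length(vars)) {
    warning("no categorical/binary columns; categorical stability is undefined",
            call. = FALSE)
    return(list(score = NA_real_, detail = tibble::tibble()))
  }
  detail <- purrr::map_dfr(vars, function(v) {
    lev <- schema$levels[schema$name == v][[1L]]
    fr <- prop.table(table(factor(real[[v]], levels = lev)))
    fa <- prop.table(table(factor(artificial[[v]], levels = lev)))
    tvd <- 0.5 * sum(abs(fr - fa))
    tibble::tibble(variable = v, tvd = tvd, stability = 100 * (1 - tvd))
  })
  list(score = mean(detail$stability), detail = detail)
}

#' @rdname stability
#' @export
correlation_stability <- function(real, artificial, schema) {
  check_cohort_pair(real, artificial, schema)
  vars <- schema$name[schema$kind == "numerical"]
  if (length(vars) < 2L) {
    warning("fewer than 2 numerical columns; correlation stability is undefined",
            call. = FALSE)
    return(list(score = NA_real_, real = NULL, artificial = NULL,
                difference = NULL))
  }
  safe_cor <- function(tab) {
    M <- as.matrix(dplyr::select(tab, dplyr::all_of(vars)))
    const <- apply(M, 2L, stats::sd) == 0
    if (any(const)) {
      warning("constant numerical column(s): ",
              paste(vars[const], collapse = ", "),
              "; their correlations are set to 0", call. = FALSE)
    }
    R <- suppressWarnings(stats::cor(M))
    R[is.na(R)] <- 0
    diag(R) <- 1
    R
  }
  R_real <- safe_cor(real)
  R_art <- safe_cor(artificial)
  diffm <- R_real - R_art
  off <- abs(diffm[upper.tri(diffm)])
  list(score = 100 * (1 - mean(off)), real = R_real, artificial = R_art,
       difference = diffm)
}

#' Composite fidelity score
#'
#' Arithmetic mean of the numerical stability, categorical stability and
#' correlation stability components, reported to one decimal (half away from
#' zero). Undefined (`NA`) components are dropped from the mean with a
#' warning.
#'
#' @param numerical,categorical,correlation Component scores in [0, 100]
#'   (percent), or `NA` for undefined.
#' @return The composite score (percent, one decimal).
#' @examples
#' fidelity_score(100, 96.4, 97.1) # 97.8
#' fidelity_score(100, 91.2, 92.6) # 94.6
#' @export
fidelity_score <- function(numerical, categorical, correlation) {
  comp <- c(numerical = numerical, categorical = categorical,
            correlation = correlation)
  if (anyNA(comp)) {
    warning("undefined component(s) dropped from the fidelity score: ",
            paste(names(comp)[is.na(comp)], collapse = ", "), call. = FALSE)
    comp <- comp[!is.na(comp)]
  }
  if (!length(comp)) return(NA_real_)
  stopifnot(all(comp >= 0), all(comp <= 100))
  round_half_away(mean(comp) * 10) / 10
}

#' Audit the fidelity of an artificial cohort
#'
#' Runs all three stability components and assembles a `fidelity_report`.
#'
#' @inheritParams stability
#' @return A `fidelity_report`: list with `fidelity_score`, the three
#'   component scores, per-variable `numerical_detail` / `categorical_detail`
#'   tibbles, and the real/artificial/difference correlation matrices.
#'   Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
audit_fidelity <- function(real, artificial, schema, alpha = 0.05) {
  num <- numerical_stability(real, artificial, schema, alpha = alpha)
  cat_ <- categorical_stability(real, artificial, schema)
  corr <- correlation_stability(real, artificial, schema)
  structure(
    list(
      fidelity_score = fidelity_score(num$score, cat_$score, corr$score),
      numerical_stability = num$score,
      categorical_stability = cat_$score,
      correlation_stability = corr$score,
      numerical_detail = num$detail,
      categorical_detail = cat_$detail,
      correlation_real = corr$real,
      correlation_artificial = corr$artificial,
      correlation_difference = corr$difference,
      n_real = nrow(real), n_artificial = nrow(artificial)
    ),
    class = "fidelity_report"
  )
}

#' @export
print.fidelity_report <- function(x, ...) {
  fmt <- function(v) format(round_half_away(v * 10) / 10, nsmall = 1)
  cat("<fidelity_report> ", x$n_real, " real vs ", x$n_artificial,
      " artificial patients\n", sep = "")
  cat("  Fidelity score:                  ", fmt(x$fidelity_score), "%\n", sep = "")
  cat("    Numerical stability:           ", fmt(x$numerical_stability), "%\n", sep = "")
  cat("    Categorical stability:         ", fmt(x$categorical_stability), "%\n", sep = "")
  cat("    Numerical correlation stability: ", fmt(x$correlation_stability), "%\n", sep = "")
  invisible(x)
}

#' @export
tidy.fidelity_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$numerical_detail, component = "numerical",
                  score = 100 * as.numeric(.data$stable)),
    dplyr::transmute(x$categorical_detail, variable = .data$variable,
                     component = "categorical", score = .data$stability)
  )
}

#' @export
glance.fidelity_report <- function(x, ...) {
  tibble::tibble(
    fidelity_score = x$fidelity_score,
    numerical_stability = x$numerical_stability,
    categorical_stability = x$categorical_stability,
    correlation_stability = x$correlation_stability,
    n_real = x$n_real, n_artificial = x$n_artificial
  )
}

check_cohort_pair <- function(real, artificial, schema) {
  stopifnot(inherits(schema, "cohort_schema"),
            is.data.frame(real), is.data.frame(artificial))
  if (!all(schema$name %in% names(real)) ||
      !all(schema$name %in% names(artificial))) {
    stop("both cohorts must contain every schema column", call. = FALSE)
  }
  if (nrow(real) == 0L || nrow(artificial) == 0L) {
    stop("cohorts must be non-empty", call. = FALSE)
  }
  invisible(TRUE)
}
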