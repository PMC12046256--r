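#' Filter similarity score: artificial records duplicating real patients
#'
#' A generated record "matches" when it equals some real record on every
#' field after decoding (numerics compared at their decoded/rounded values,
#' levels exactly). The score is the percentage of artificial records that do
#' NOT match any real record — 100 means no artificial patient duplicates a
#' real one. An optional relaxed mode additionally flags artificial records
#' whose Euclidean distance to the nearest real record in the min-max-scaled
#' encoded space falls below `epsilon`.
#'
#' @param real,artificial Schema-conforming tibbles sharing `schema`.
#' @param schema A [cohort_schema()].
#' @param epsilon Optional distance threshold for the relaxed match mode
#'   (default `NULL`: exact equality only).
#' @return List with `score` (percent), `n_matches`, and `matches` (tibble of
#'   offending artificial row indices).
#' @export
filter_similarity <- function(real, artificial, schema, epsilon = NULL) {
  check_cohort_pair(real, artificial, schema)
  art <- dplyr::mutate(artificial[schema$name],
                       .row = dplyr::row_number())
  hits <- dplyr::semi_join(art, real[schema$name], by = schema$name)
  match_rows <- hits$.row
  if (!is.null(epsilon)) {
    enc <- fit_transform(real, schema)
    D <- cross_dist(apply_transform(enc, artificial), enc$values)
    match_rows <- sort(union(match_rows,
                             which(apply(D, 1L, min) < epsilon)))
  }
  n <- nrow(artificial)
  list(score = 100 * (1 - length(match_rows) / n),
       n_matches = length(match_rows),
       matches = tibble::tibble(artificial_row = match_rows))
}

# pairwise Euclidean distances between rows of A (n x d) and B (m x d)
cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' Degree of anonymization: nearest-neighbour distance audit
#'
#' Compares, in the min-max-scaled encoded space (so no single wide-range
#' numeric dominates the Euclidean metric), each artificial record's distance
#' to its nearest real record against each real record's distance to its
#' nearest *other* real record (leave-one-out). The cohort counts as
#' anonymized when the median artificial-to-real distance is at least the
#' median real leave-one-out distance: artificial patients then sit farther
#' from real patients than real patients sit from each other.
#'
#' @inheritParams filter_similarity
#' @param encoded Optional `encoded_cohort` fitted on `real` (recomputed when
#'   missing); its scaler state defines the shared encoding.
#' @return List with the two nearest-neighbour distance samples
#'   (`nn_art_to_real`, `nn_real_loo`), their medians, `ratio`
#'   (median art-to-real over median leave-one-out) and the `anonymized`
#'   flag (`ratio >= 1`).
#' @export
anonymization_degree <- function(real, artificial, schema, encoded = NULL) {
  check_cohort_pair(real, artificial, schema)
  if (nrow(real) < 2L) {
    stop("leave-one-out distances need at least 2 real records", call. = FALSE)
  }
  enc <- encoded %||% fit_transform(real, schema)
  R <- if (is.null(encoded)) enc$values else apply_transform(enc, real)
  A <- apply_transform(enc, artificial)
  D_ar <- cross_dist(A, R)
  nn_art <- apply(D_ar, 1L, min)
  D_rr <- cross_dist(R, R)
  diag(D_rr) <- Inf
  nn_loo <- apply(D_rr, 1L, min)
  med_art <- stats::median(nn_art)
  med_loo <- stats::median(nn_loo)
  list(nn_art_to_real = nn_art, nn_real_loo = nn_loo,
       median_art_to_real = med_art, median_real_loo = med_loo,
       ratio = med_art / med_loo, anonymized = med_art / med_loo >= 1)
}

#' Run the full confidentiality audit
#'
#' @inheritParams anonymization_degree
#' @param epsilon Optional relaxed-match threshold for [filter_similarity()].
#' @return A `privacy_report` combining the filter similarity score and the
#'   anonymization distances; supports `tidy()`/`glance()`.
#' @export
audit_privacy <- function(real, artificial, schema, encoded = NULL,
                          epsilon = NULL) {
  fs <- filter_similarity(real, artificial, schema, epsilon = epsilon)
  an <- anonymization_degree(real, artificial, schema, encoded = encoded)
  structure(
    c(list(filter_similarity_score = fs$score, n_exact_matches = fs$n_matches,
           matches = fs$matches), an,
      list(n_real = nrow(real), n_artificial = nrow(artificial))),
    class = "privacy_report"
  )
}

#' @export
print.privacy_report <- function(x, ...) {
  cat("<privacy_report> ", x$n_real, " real vs ", x$n_artificial,
      " artificial patients\n", sep = "")
  cat("  Filter similarity score: ",
      format(round(x$filter_similarity_score, 2), nsmall = 1), "% (",
      x$n_exact_matches, " matching records)\n", sep = "")
  cat("  Median NN distance, artificial to real: ",
      format(x$median_art_to_real, digits = 4), "\n", sep = "")
  cat("  Median NN distance, real leave-one-out: ",
      format(x$median_real_loo, digits = 4), "\n", sep = "")
  cat("  Anonymized: ", x$anonymized, " (ratio ",
      format(x$ratio, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.privacy_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(sample = "artificial_to_real", distance = x$nn_art_to_real),
    tibble::tibble(sample = "real_leave_one_out", distance = x$nn_real_loo)
  )
}

#' @export
glance.privacy_report <- function(x, ...) {
  tibble::tibble(
    filter_similarity_score = x$filter_similarity_score,
    n_exact_matches = x$n_exact_matches,
    median_art_to_real = x$median_art_to_real,
    median_real_loo = x$median_real_loo,
    anonymization_ratio = x$ratio,
    anonymized = x$anonymized
  )
}
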