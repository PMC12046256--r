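#' Run the full consistency + confidentiality audit
#'
#' One call computing the fidelity report (distribution and correlation
#' stability) and the privacy report (filter similarity, degree of
#' anonymization) of an artificial cohort against the real cohort it was
#' generated from.
#'
#' @inheritParams audit_fidelity
#' @param encoded Optional `encoded_cohort` fitted on `real` (avoids a refit).
#' @param epsilon Optional relaxed-match threshold for [filter_similarity()].
#' @return An `audit_report`: list with elements `fidelity` (a
#'   `fidelity_report`) and `privacy` (a `privacy_report`). Supports
#'   `glance()` (one row with all headline scores).
#' @export
audit_cohorts <- function(real, artificial, schema, encoded = NULL,
                          alpha = 0.05, epsilon = NULL) {
  structure(
    list(
      fidelity = audit_fidelity(real, artificial, schema, alpha = alpha),
      privacy = audit_privacy(real, artificial, schema, encoded = encoded,
                              epsilon = epsilon)
    ),
    class = "audit_report"
  )
}

#' @export
print.audit_report <- function(x, ...) {
  print(x$fidelity)
  print(x$privacy)
  invisible(x)
}

#' @export
glance.audit_report <- function(x, ...) {
  dplyr::bind_cols(glance(x$fidelity), glance(x$privacy))
}

#' Write an audit report to disk
#'
#' Emits a machine-readable JSON report and a Markdown summary whose fidelity
#' table mirrors the composite-then-components layout (score, numerical
#' stability, categorical stability, numerical correlation stability), plus
#' the confidentiality section.
#'
#' @param report An `audit_report` from [audit_cohorts()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_audit_report <- function(report, dir) {
  stopifnot(inherits(report, "audit_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fid <- report$fidelity
  priv <- report$privacy
  json_path <- file.path(dir, "audit_report.json")
  jsonlite::write_json(
    list(
      fidelity = list(
        fidelity_score = fid$fidelity_score,
        numerical_stability = fid$numerical_stability,
        categorical_stability = fid$categorical_stability,
        correlation_stability = fid$correlation_stability,
        numerical_detail = fid$numerical_detail,
        categorical_detail = fid$categorical_detail
      ),
      privacy = list(
        filter_similarity_score = priv$filter_similarity_score,
        n_exact_matches = priv$n_exact_matches,
        median_art_to_real = priv$median_art_to_real,
        median_real_loo = priv$median_real_loo,
        anonymization_ratio = priv$ratio,
        anonymized = priv$anonymized
      ),
      n_real = fid$n_real, n_artificial = fid$n_artificial
    ),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  fmt1 <- function(v) format(round_half_away(v * 10) / 10, nsmall = 1)
  md <- c(
    "# Artificial cohort audit",
    "",
    sprintf("%d real vs %d artificial patients.", fid$n_real, fid$n_artificial),
    "",
    "## Consistency (fidelity)",
    "",
    "| Scores | % |",
    "|---|---|",
    sprintf("| **Fidelity score** | %s |", fmt1(fid$fidelity_score)),
    sprintf("| Numerical stability | %s |", fmt1(fid$numerical_stability)),
    sprintf("| Categorical stability | %s |", fmt1(fid$categorical_stability)),
    sprintf("| Numerical correlation stability | %s |",
            fmt1(fid$correlation_stability)),
    "",
    "## Confidentiality",
    "",
    sprintf("- Filter similarity score: %s%% (%d artificial records duplicate a real record)",
            fmt1(priv$filter_similarity_score), priv$n_exact_matches),
    sprintf("- Median NN distance, artificial to real: %.4f", priv$median_art_to_real),
    sprintf("- Median NN distance, real leave-one-out: %.4f", priv$median_real_loo),
    sprintf("- Degree of anonymization: ratio %.3f -> %s", priv$ratio,
            if (priv$anonymized) "anonymized" else "NOT anonymized"),
    ""
  )
  md_path <- file.path(dir, "audit_report.md")
  writeLines(md, md_path)
  invisible(c(json_path, md_path))
}
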