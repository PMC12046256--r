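#' Cohen's kappa for a blinded real-vs-artificial categorization task
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} between a
#' rater's real/artificial calls and the ground truth, with an asymptotic
#' 95% confidence interval (large-sample standard error of Fleiss, Cohen &
#' Everitt). Agreement below 0.2 is interpreted as the rater being unable to
#' distinguish artificial from real patients.
#'
#' @param rater Factor/character vector of the rater's calls.
#' @param truth Ground-truth labels, same length; both inputs must use the
#'   same two labels (e.g. `"real"`/`"artificial"`).
#' @param conf_level Confidence level of the interval (default 0.95).
#' @return A `kappa_result`: list with `kappa`, `ci_low`, `ci_high`, `se`,
#'   `n_items`, `p_observed`, `p_expected`, `interpretation`
#'   (`"indistinguishable"` below 0.2, `"partial"` in [0.2, 0.6),
#'   `"distinguishable"` at or above 0.6). Supports `tidy()`.
#' @examples
#' truth <- rep(c("real", "artificial"), 50)
#' cohen_kappa(truth, truth)$kappa # 1
#' @export
cohen_kappa <- function(rater, truth, conf_level = 0.95) {
  stopifnot(length(rater) == length(truth))
  n <- length(truth)
  if (n < 10L) stop("kappa needs at least 10 items", call. = FALSE)
  labels <- sort(unique(c(as.character(rater), as.character(truth))))
  if (length(labels) > 2L) {
    stop("labels must be binary; got: ", paste(labels, collapse = ", "),
         call. = FALSE)
  }
  r <- factor(as.character(rater), levels = labels)
  t_ <- factor(as.character(truth), levels = labels)
  P <- table(r, t_) / n
  po <- sum(diag(P))
  pr <- rowSums(P); pc <- colSums(P)
  pe <- sum(pr * pc)
  if (pe >= 1 - .Machine$double.eps^0.5) {
    stop("degenerate marginals (expected agreement 1); kappa is undefined",
         call. = FALSE)
  }
  k <- (po - pe) / (1 - pe)
  # Fleiss-Cohen-Everitt large-sample variance
  A <- sum(diag(P) * (1 - (pr + pc) * (1 - k))^2)
  B <- 0
  for (i in seq_along(labels)) {
    for (j in seq_along(labels)) {
      if (i != j) B <- B + P[i, j] * (pc[i] + pr[j])^2
    }
  }
  B <- (1 - k)^2 * B
  C <- (k - pe * (1 - k))^2
  se <- sqrt(pmax(A + B - C, 0)) / ((1 - pe) * sqrt(n))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  interp <- if (k < 0.2) "indistinguishable" else if (k < 0.6) "partial" else "distinguishable"
  structure(
    list(kappa = unname(k), ci_low = unname(k - zq * se),
         ci_high = unname(k + zq * se), se = unname(se), n_items = n,
         p_observed = unname(po), p_expected = unname(pe),
         interpretation = interp, conf_level = conf_level),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat("Cohen's kappa: ", format(round(x$kappa, 2), nsmall = 2), " (",
      round(100 * x$conf_level), "% CI ",
      format(round(x$ci_low, 2), nsmall = 2), " to ",
      format(round(x$ci_high, 2), nsmall = 2), "), n = ", x$n_items,
      " -> ", x$interpretation, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.kappa_result <- function(x, ...) {
  tibble::tibble(kappa = x$kappa, ci_low = x$ci_low, ci_high = x$ci_high,
                 se = x$se, n_items = x$n_items,
                 interpretation = x$interpretation)
}

#' Build a blinded categorization sheet for expert raters
#'
#' Samples a balanced set of patients (half real, half artificial), shuffles
#' them, and returns the blinded sheet raters see plus the hidden key that
#' [cohen_kappa()] consumes once the completed sheets come back.
#'
#' @param real,artificial Schema-conforming cohorts.
#' @param n_items Total number of items (must be even; default 100, i.e. 50
#'   real + 50 artificial).
#' @param seed Seed controlling sampling and shuffling.
#' @return List with `sheet` (tibble: `item_id` plus all patient columns, in
#'   shuffled order) and `key` (tibble: `item_id`, `truth`).
#' @export
categorization_sheet <- function(real, artificial, n_items = 100, seed = 1) {
  stopifnot(is.data.frame(real), is.data.frame(artificial))
  if (n_items %% 2 != 0) {
    stop("n_items must be even (the sample is balanced)", call. = FALSE)
  }
  half <- n_items / 2
  if (nrow(real) < half || nrow(artificial) < half) {
    stop("each cohort needs at least n_items/2 = ", half, " rows", call. = FALSE)
  }
  set.seed(seed)
  ri <- sample.int(nrow(real), half)
  ai <- sample.int(nrow(artificial), half)
  pool <- dplyr::bind_rows(
    dplyr::mutate(real[ri, ], .truth = "real"),
    dplyr::mutate(artificial[ai, ], .truth = "artificial")
  )
  pool <- pool[sample.int(n_items), ]
  pool$item_id <- sprintf("item_%03d", seq_len(n_items))
  key <- tibble::tibble(item_id = pool$item_id, truth = pool$.truth)
  sheet <- dplyr::select(pool, "item_id", !dplyr::any_of(c(".truth", "item_id")))
  list(sheet = tibble::as_tibble(sheet), key = key)
}
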