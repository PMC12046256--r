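#' Overlay the real and artificial distribution of one variable
#'
#' Numerical variables are shown as overlaid relative-frequency histograms;
#' binary/categorical variables as side-by-side relative-percentage bars —
#' the per-variable view used to eyeball distribution stability.
#'
#' @param real,artificial Schema-conforming cohorts.
#' @param schema A [cohort_schema()].
#' @param variable Column name to plot.
#' @param bins Histogram bin count for numerical variables.
#' @return A ggplot object; its `$data` holds the plotted series (cohort,
#'   value / level, percent).
#' @export
plot_distribution_overlay <- function(real, artificial, schema, variable,
                                      bins = 30) {
  check_cohort_pair(real, artificial, schema)
  stopifnot(variable %in% schema$name)
  kind <- schema$kind[schema$name == variable]
  if (kind == "numerical") {
    df <- dplyr::bind_rows(
      tibble::tibble(cohort = "real", value = real[[variable]]),
      tibble::tibble(cohort = "artificial", value = artificial[[variable]])
    )
    breaks <- seq(min(df$value), max(df$value), length.out = bins + 1L)
    if (breaks[1L] == breaks[bins + 1L]) breaks <- breaks[1L] + c(-0.5, 0.5)
    series <- df |>
      dplyr::mutate(bin = cut(.data$value, breaks = unique(breaks),
                              include.lowest = TRUE)) |>
      dplyr::count(.data$cohort, .data$bin) |>
      dplyr::group_by(.data$cohort) |>
      dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup()
    ggplot2::ggplot(series,
                    ggplot2::aes(x = .data$bin, y = .data$percent,
                                 fill = .data$cohort)) +
      ggplot2::geom_col(position = "identity", alpha = 0.55) +
      ggplot2::labs(x = variable, y = "patients (%)", fill = NULL) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  } else {
    lev <- schema$levels[schema$name == variable][[1L]]
    series <- dplyr::bind_rows(
      tibble::tibble(cohort = "real",
                     level = factor(as.character(real[[variable]]), lev)),
      tibble::tibble(cohort = "artificial",
                     level = factor(as.character(artificial[[variable]]), lev))
    ) |>
      dplyr::count(.data$cohort, .data$level, .drop = FALSE) |>
      dplyr::group_by(.data$cohort) |>
      dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup()
    ggplot2::ggplot(series,
                    ggplot2::aes(x = .data$level, y = .data$percent,
                                 fill = .data$cohort)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = variable, y = "patients (%)", fill = NULL) +
      ggplot2::theme_minimal()
  }
}

#' Plot a fidelity report
#'
#' `type = "correlation"` shows the real, artificial and difference
#' correlation matrices of the numerical variables as heatmaps;
#' `type = "components"` shows the three stability components and the
#' composite score as bars.
#'
#' @param object A `fidelity_report` from [audit_fidelity()].
#' @param type `"correlation"` or `"components"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fidelity_report <- function(object, type = c("correlation", "components"),
                                     ...) {
  type <- match.arg(type)
  if (type == "components") {
    df <- tibble::tibble(
      component = factor(
        c("numerical", "categorical", "correlation", "fidelity score"),
        levels = c("numerical", "categorical", "correlation", "fidelity score")
      ),
      score = c(object$numerical_stability, object$categorical_stability,
                object$correlation_stability, object$fidelity_score)
    )
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$score)) +
        ggplot2::geom_col(fill = "steelblue") +
        ggplot2::coord_cartesian(ylim = c(0, 100)) +
        ggplot2::labs(x = NULL, y = "stability (%)") +
        ggplot2::theme_minimal()
    )
  }
  if (is.null(object$correlation_real)) {
    stop("report holds no correlation matrices", call. = FALSE)
  }
  melt <- function(M, which) {
    tibble::tibble(
      row = factor(rep(rownames(M), times = ncol(M)), levels = rownames(M)),
      col = factor(rep(colnames(M), each = nrow(M)), levels = colnames(M)),
      r = as.vector(M), panel = which
    )
  }
  df <- dplyr::bind_rows(
    melt(object$correlation_real, "real"),
    melt(object$correlation_artificial, "artificial"),
    melt(object$correlation_difference, "difference")
  )
  df$panel <- factor(df$panel, levels = c("real", "artificial", "difference"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                                  limits = c(-1, 1), name = "r") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_text(size = 5),
                   axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}

#' Write per-variable comparison plots and correlation heatmaps to disk
#'
#' One distribution overlay per schema variable plus the three correlation
#' heatmaps, as PNG or SVG files.
#'
#' @inheritParams plot_distribution_overlay
#' @param dir Output directory (created if needed).
#' @param format `"png"` or `"svg"`.
#' @param width,height,dpi Device settings passed to [ggplot2::ggsave()].
#' @return Invisibly, the written file paths.
#' @export
render_comparisons <- function(real, artificial, schema, dir, format = "png",
                               width = 6, height = 4, dpi = 120) {
  check_cohort_pair(real, artificial, schema)
  stopifnot(format %in% c("png", "svg"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L) {
    stop("output directory '", dir, "' is not writable", call. = FALSE)
  }
  files <- character(0)
  for (v in schema$name) {
    p <- plot_distribution_overlay(real, artificial, schema, v)
    f <- file.path(dir, paste0("dist_", v, ".", format))
    suppressMessages(ggplot2::ggsave(f, p, width = width, height = height,
                                     dpi = dpi))
    files <- c(files, f)
  }
  rep_ <- audit_fidelity(real, artificial, schema)
  if (!is.null(rep_$correlation_real)) {
    mats <- list(real = rep_$correlation_real,
                 artificial = rep_$correlation_artificial,
                 difference = rep_$correlation_difference)
    for (nm in names(mats)) {
      one <- autoplot(rep_, type = "correlation")
      one$data <- one$data[one$data$panel == nm, ]
      f <- file.path(dir, paste0("correlation_", nm, ".", format))
      suppressMessages(ggplot2::ggsave(f, one, width = 6, height = 5, dpi = dpi))
      files <- c(files, f)
    }
  }
  invisible(files)
}
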