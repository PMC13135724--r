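#' Plot LOY percentage along pseudotime quantiles
#'
#' Line plot of the per-quantile LOY percentage, one line per lineage (or
#' cell type), the standard visual for trajectory-gradient results.
#'
#' @param cells tibble with `loy`, `quantile` and a grouping column.
#' @param group grouping column name (default `"lineage"`).
#' @export
plot_quantile_loy <- function(cells, group = "lineage") {
  df <- cells |>
    dplyr::filter(!is.na(.data$loy), !is.na(.data$quantile)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group, "quantile")))) |>
    dplyr::summarise(pct_loy = 100 * mean(.data$loy), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$quantile, .data$pct_loy,
                                   colour = .data[[group]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = 1:6) +
    ggplot2::labs(x = "pseudotime quantile", y = "% LOY cells",
                  colour = group) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.loy_age_assoc <- function(object, ...) {
  df <- object$fit$model
  df$age <- df$age
  ggplot2::ggplot(df, ggplot2::aes(.data$age, .data$elogit)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "red") +
    ggplot2::labs(x = "donor age (years)",
                  y = "empirical logit of % LOY cells") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression table
#'
#' @param de tibble from [hurdle_de()].
#' @param alpha adjusted-significance threshold to highlight.
#' @export
plot_volcano <- function(de, alpha = 0.05) {
  ggplot2::ggplot(de, ggplot2::aes(.data$avg_log2fc,
                                   -log10(pmax(.data$p_adj, 1e-300)),
                                   colour = .data$p_adj < alpha)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "average log2 fold change (LOY vs non-LOY)",
                  y = "-log10 adjusted p", colour = "significant") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
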