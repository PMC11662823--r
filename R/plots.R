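# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano-style plot of a group enrichment result
#'
#' @param object A `lakemicrodiv_enrichment` table.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.lakemicrodiv_enrichment <- function(object, ...) {
  groups <- attr(object, "groups")
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(
      difference = .data$mean_group1 - .data$mean_group2,
      neglog_q = -log10(pmax(.data$q_value, 1e-300)),
      call = dplyr::coalesce(.data$enriched_in, "not enriched")
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$difference, .data$neglog_q,
                                   color = .data$call)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(
      yintercept = -log10(attr(object, "fdr_threshold")), linetype = 2
    ) +
    ggplot2::labs(
      x = sprintf("mean(%s) - mean(%s)", groups[1], groups[2]),
      y = expression(-log[10] ~ q),
      color = "enriched in"
    ) +
    ggplot2::theme_minimal()
}

#' Group-wise distribution of a population-genetic statistic
#'
#' @param popgen Popgen summary tibble (e.g. from [run_pipeline()]).
#' @param metadata Tibble with `sample_id` and `group`.
#' @param stat Column of `popgen` to plot (default `pn_ps`).
#' @return A ggplot (violin + jitter per group, QC-passing pairs only).
#' @export
plot_popgen_groups <- function(popgen, metadata, stat = "pn_ps") {
  df <- popgen |>
    dplyr::filter(.data$qc_pass, !is.na(.data[[stat]])) |>
    dplyr::inner_join(metadata[, c("sample_id", "group")], by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data[[stat]],
                                   fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.5, scale = "width") +
    ggplot2::geom_jitter(width = 0.12, size = 0.8, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = stat) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Assembly-process composition plot
#'
#' @param class_tbl Output of [assembly_classes()].
#' @return A ggplot bar chart of assembly-class fractions.
#' @export
plot_assembly_classes <- function(class_tbl) {
  df <- class_tbl |>
    dplyr::filter(!is.na(.data$assembly_class)) |>
    dplyr::count(.data$assembly_class) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
  ggplot2::ggplot(df, ggplot2::aes(.data$assembly_class, .data$fraction,
                                   fill = .data$assembly_class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of sample pairs") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
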