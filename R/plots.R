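#' Scatter plot of two expression modes
#'
#' Plots one expression mode against another on `log2(value + pseudo)` axes,
#' with the identity line for reference.
#'
#' @param table_x,table_y Expression tables (tibbles with `feature_id`,
#'   `sample`, `value`, `mode`); joined on feature and sample.
#' @param pseudo Pseudo-count for the log axes (default 0.5).
#' @return A ggplot object.
#' @export
plot_rpkm_scatter <- function(table_x, table_y, pseudo = 0.5) {
  df <- inner_join(
    table_x |> select("feature_id", "sample", x = "value"),
    table_y |> select("feature_id", "sample", y = "value"),
    by = c("feature_id", "sample")
  )
  ggplot2::ggplot(df, ggplot2::aes(log_shift(.data$x, pseudo),
                                   log_shift(.data$y, pseudo))) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$sample)) +
    ggplot2::labs(
      x = paste0("log2(", table_x$mode[1], " + ", pseudo, ")"),
      y = paste0("log2(", table_y$mode[1], " + ", pseudo, ")")
    ) +
    ggplot2::theme_bw()
}

#' Cumulative distribution plot of expression ratios
#'
#' @param ratio_tbl A [ratio_table()] result.
#' @return A ggplot object (step ECDF, log-scaled ratio axis).
#' @export
plot_ratio_ecdf <- function(ratio_tbl) {
  ggplot2::ggplot(ratio_tbl, ggplot2::aes(.data$ratio, colour = .data$sample)) +
    ggplot2::stat_ecdf(geom = "step") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "rsem_txSum_rpkm / rsem_rpkm (background-adjusted)",
                  y = "cumulative fraction of genes") +
    ggplot2::theme_bw()
}

#' Ratio distributions across structural bins
#'
#' Boxplots of the per-gene expression ratio within bins of a structural
#' feature (number of union exons or of annotated isoforms).
#'
#' @param ratio_tbl A [ratio_table()] result.
#' @param ann A `tx_annotation`.
#' @param feature `"n_transcripts"` (default) or `"n_union_exons"`.
#' @param n_bins Number of bins (default 10).
#' @return A ggplot object.
#' @export
plot_ratio_bins <- function(ratio_tbl, ann,
                            feature = c("n_transcripts", "n_union_exons"),
                            n_bins = 10L) {
  feature <- match.arg(feature)
  bins <- bin_by_structure(ratio_tbl, ann, feature, n_bins)
  df <- ratio_tbl |>
    inner_join(structural_features(ann), by = c(feature_id = "gene_id")) |>
    mutate(feature_value = .data[[feature]])
  # reuse the bin edges: assign each gene to its bin by feature range
  df$bin <- NA_integer_
  for (i in seq_len(nrow(bins))) {
    hit <- df$feature_value >= bins$feature_min[i] &
      df$feature_value <= bins$feature_max[i]
    df$bin[hit] <- bins$bin[i]
  }
  df$bin_label <- factor(
    df$bin, levels = bins$bin,
    labels = ifelse(bins$feature_min == bins$feature_max,
                    bins$feature_min,
                    paste0(bins$feature_min, "-", bins$feature_max))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_label, .data$ratio)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = feature, y = "rsem_txSum_rpkm / rsem_rpkm") +
    ggplot2::theme_bw()
}
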