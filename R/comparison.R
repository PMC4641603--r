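#' Background-adjusted expression ratio
#'
#' The headline per-gene statistic: the ratio of transcript-sum RPKM to
#' union-length RPKM. A small background `b` is added to both numerator and
#' denominator before dividing, so zero expression gives a ratio of exactly 1
#' instead of 0/0. With the published values for gene HAMP
#' (`txsum = 15.49`, `rsem = 3.81`), the ratio is 4.06 at two decimals.
#'
#' @param txsum Transcript-sum RPKM values (`rsem_txSum_rpkm`).
#' @param rsem Union-length RPKM values (`rsem_rpkm`).
#' @param background Background value added to both (default 0.01).
#' @return `(txsum + background) / (rsem + background)`.
#' @export
expression_ratio <- function(txsum, rsem, background = 0.01) {
  if (any(txsum < 0) || any(rsem < 0)) abort("RPKM values must be non-negative")
  (txsum + background) / (rsem + background)
}

#' Per-gene ratio table
#'
#' Joins the transcript-sum and union-length expression tables and computes
#' the background-adjusted ratio per gene and sample.
#'
#' @param txsum_table Expression table with mode `rsem_txSum_rpkm`
#'   ([gene_rpkm_txsum()] output).
#' @param rsem_table Expression table with mode `rsem_rpkm`
#'   ([gene_rpkm_union()] output).
#' @param background Background value (default 0.01).
#' @return A tibble `feature_id`, `sample`, `rsem_txSum_rpkm`, `rsem_rpkm`,
#'   `ratio`.
#' @export
ratio_table <- function(txsum_table, rsem_table, background = 0.01) {
  inner_join(
    txsum_table |> select("feature_id", "sample", rsem_txSum_rpkm = "value"),
    rsem_table |> select("feature_id", "sample", rsem_rpkm = "value"),
    by = c("feature_id", "sample")
  ) |>
    mutate(ratio = expression_ratio(.data$rsem_txSum_rpkm, .data$rsem_rpkm,
                                    background))
}

#' Cumulative distribution of expression ratios
#'
#' Step ECDF of the per-gene ratios: for each observed ratio, the fraction of
#' genes at or below it.
#'
#' @param ratios Numeric vector of ratios (e.g. `ratio_table(...)$ratio`).
#' @return A tibble `ratio`, `cum_fraction`, sorted by ratio;
#'   `cum_fraction` is non-decreasing and ends at 1.
#' @export
cumulative_ratio_distribution <- function(ratios) {
  stopifnot(length(ratios) > 0, all(is.finite(ratios)))
  s <- sort(ratios)
  tibble(ratio = unique(s),
         cum_fraction = cumsum(tabulate(match(s, unique(s)))) / length(s))
}

#' Summarize ratios in bins of a structural feature
#'
#' Sorts genes by a structural feature (number of union exons or number of
#' annotated isoforms) and cuts them into `n_bins` bins of comparable size.
#' Genes sharing a feature value always land in the same bin (ties are never
#' split), so bins may be fewer than requested when few distinct values
#' exist.
#'
#' @param ratio_tbl A [ratio_table()] result (uses `feature_id` and `ratio`;
#'   multi-sample tables pool all samples).
#' @param ann A `tx_annotation` supplying the structural features.
#' @param feature `"n_transcripts"` (default) or `"n_union_exons"`.
#' @param n_bins Number of bins (default 10).
#' @return A tibble with one row per bin: `bin`, `feature_min`,
#'   `feature_max`, `n_genes`, `mean_ratio`, `median_ratio`, `q1`, `q3`.
#' @export
bin_by_structure <- function(ratio_tbl, ann,
                             feature = c("n_transcripts", "n_union_exons"),
                             n_bins = 10L) {
  feature <- match.arg(feature)
  stopifnot(inherits(ann, "tx_annotation"), n_bins >= 1)
  df <- ratio_tbl |>
    inner_join(structural_features(ann), by = c(feature_id = "gene_id")) |>
    mutate(feature_value = .data[[feature]]) |>
    arrange(.data$feature_value)
  if (nrow(df) == 0) abort("no genes to bin")
  # bin distinct feature values by the mid-rank of their gene block, so ties
  # stay together and bin sizes are as even as the ties allow
  val_tbl <- df |>
    count(.data$feature_value, name = "n") |>
    arrange(.data$feature_value) |>
    mutate(
      cum_end = cumsum(.data$n),
      cum_mid = .data$cum_end - .data$n / 2,
      bin = pmin(.env$n_bins, ceiling(.data$cum_mid / (sum(.data$n) / .env$n_bins)))
    ) |>
    mutate(bin = as.integer(factor(.data$bin)))  # renumber consecutively
  df |>
    inner_join(val_tbl |> select("feature_value", "bin"), by = "feature_value") |>
    group_by(.data$bin) |>
    summarise(
      feature_min = min(.data$feature_value),
      feature_max = max(.data$feature_value),
      n_genes = dplyr::n(),
      mean_ratio = mean(.data$ratio),
      median_ratio = median(.data$ratio),
      q1 = unname(quantile(.data$ratio, 0.25)),
      q3 = unname(quantile(.data$ratio, 0.75)),
      .groups = "drop"
    ) |>
    mutate(feature = .env$feature, .before = 1)
}

#' Per-sample ratio of total counted reads
#'
#' Total reads counted by the union-exon counter divided by total reads
#' counted by the transcript-based quantifier, per sample. With
#' intron-retention reads present (counted by the partial-overlap rule,
#' dropped by the strict-compatibility rule) this ratio exceeds 1; at a 4%
#' intron-retention share it is about 1.042.
#'
#' @param fc_counts Tibble `gene_id`, `sample`, `count` (union counting).
#' @param rsem_counts Tibble `gene_id`, `sample`, `rsem_count` (or `count`).
#' @return A tibble `sample`, `fc_total`, `rsem_total`, `ratio`.
#' @export
count_ratio <- function(fc_counts, rsem_counts) {
  rsem_counts <- as_tibble(rsem_counts)
  if (!"rsem_count" %in% names(rsem_counts)) {
    rsem_counts <- rsem_counts |> rename(rsem_count = "count")
  }
  out <- inner_join(
    fc_counts |> group_by(.data$sample) |>
      summarise(fc_total = sum(.data$count), .groups = "drop"),
    rsem_counts |> group_by(.data$sample) |>
      summarise(rsem_total = sum(.data$rsem_count), .groups = "drop"),
    by = "sample"
  )
  if (any(out$rsem_total <= 0)) {
    abort("total transcript-based count is zero in at least one sample")
  }
  out |> mutate(ratio = .data$fc_total / .data$rsem_total)
}

#' Per-sample mean expression by mode
#'
#' Averages an expression table over features within each sample -- the
#' summary on which the underestimation test operates.
#'
#' @param ... Expression tables (tibbles with `sample`, `value`, `mode`).
#' @return A tibble `mode`, `sample`, `mean_value`.
#' @export
mean_expression <- function(...) {
  bind_rows(...) |>
    group_by(.data$mode, .data$sample) |>
    summarise(mean_value = mean(.data$value), .groups = "drop")
}

#' Paired test for union-exon underestimation
#'
#' Two-sided paired t-test comparing per-sample mean expression under the
#' transcript-sum mode against the union-length mode, pairing on sample. A
#' significant positive difference indicates that union-exon quantification
#' systematically underestimates gene expression.
#'
#' @param mean_txsum,mean_union Numeric vectors of per-sample means, in the
#'   same sample order (length >= 2).
#' @return A tibble `estimate` (mean difference txsum - union), `statistic`,
#'   `df`, `p_value`.
#' @export
underestimation_test <- function(mean_txsum, mean_union) {
  if (length(mean_txsum) < 2 || length(mean_txsum) != length(mean_union)) {
    abort("need >= 2 paired per-sample means")
  }
  d <- mean_txsum - mean_union
  if (sd(d) == 0) {
    # degenerate but well-defined: constant difference
    stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(tibble(
      estimate = mean(d), statistic = stat, df = length(d) - 1,
      p_value = if (mean(d) == 0) 1 else 0
    ))
  }
  ht <- t.test(mean_txsum, mean_union, paired = TRUE)
  tibble(
    estimate = unname(ht$estimate),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value
  )
}
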