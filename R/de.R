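#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up: sort p-values ascending, take
#' `q_i = min_{j >= i} p_j * m / j`, cap at 1, and restore input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]` (NAs preserved).
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(pvalues))
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  m <- length(p)
  if (m == 0) return(out)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * m / seq(m, 1)))
  out[ok] <- q[order(o)]
  out
}

# pooled two-sample t-test on rows; returns two-sided p-values
.row_t_test <- function(x_mat, y_mat) {
  n1 <- ncol(x_mat); n2 <- ncol(y_mat)
  m1 <- rowMeans(x_mat); m2 <- rowMeans(y_mat)
  v1 <- apply(x_mat, 1, stats::var); v2 <- apply(y_mat, 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  stat <- (m2 - m1) / se
  p <- 2 * pt(-abs(stat), df = n1 + n2 - 2)
  # degenerate rows: zero pooled variance
  flat <- se == 0
  p[flat & m1 == m2] <- 1
  p[flat & m1 != m2] <- 0
  p
}

#' Two-group differential expression call
#'
#' A simple, documented stand-in for a full count-model analysis: counts are
#' converted to CPM, a two-sample pooled t-test is run per feature on
#' `log2(CPM + 0.5)` (or a user-supplied `test_fn`), p-values are adjusted by
#' [bh_adjust()], and a feature is flagged DE when its fold change reaches
#' `fc_threshold` (as `|log2FC| >= log2(fc_threshold)`) and its adjusted
#' p-value is below `alpha`. Fold changes are computed from group mean CPMs
#' (second condition over first, alphabetically) with a 0.5 pseudo-count.
#'
#' The statistical test is deliberately pluggable so that externally computed
#' per-feature p-values (e.g. from a negative-binomial model) can be used via
#' [de_from_stats()]; the analysis of interest here is the downstream set
#' comparison, not the test itself.
#'
#' @param counts Tibble `feature_id`, `sample`, `count`.
#' @param design Tibble `sample`, `condition` with exactly two conditions and
#'   at least two replicates each.
#' @param level `"gene"` or `"transcript"`; recorded on the result.
#' @param test_fn Optional `function(x, y) -> p-value` applied per feature to
#'   the two groups' log2-CPM vectors; default is the vectorized pooled
#'   t-test.
#' @param fc_threshold Fold-change threshold (default 1.5).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return A list of class `de_result` with `table` (tibble `feature_id`,
#'   `mean_cpm_1`, `mean_cpm_2`, `log2fc`, `p_value`, `adj_p`, `de`),
#'   `level`, `conditions`, `fc_threshold`, `alpha`.
#' @export
de_call <- function(counts, design, level = c("gene", "transcript"),
                    test_fn = NULL, fc_threshold = 1.5, alpha = 0.05) {
  level <- match.arg(level)
  counts <- as_tibble(counts)
  if ("gene_id" %in% names(counts) && !"feature_id" %in% names(counts)) {
    counts <- counts |> rename(feature_id = "gene_id")
  }
  if ("transcript_id" %in% names(counts) && !"feature_id" %in% names(counts)) {
    counts <- counts |> rename(feature_id = "transcript_id")
  }
  stopifnot(all(c("feature_id", "sample", "count") %in% names(counts)))
  design <- as_tibble(design)
  conds <- sort(unique(design$condition))
  if (length(conds) != 2) abort("design must contain exactly two conditions")
  reps <- design |> count(.data$condition)
  if (any(reps$n < 2)) abort("each condition needs at least two replicates")

  lib <- counts |>
    group_by(.data$sample) |>
    summarise(lib = sum(.data$count), .groups = "drop")
  if (any(lib$lib <= 0)) abort("a sample has zero library size")

  cpm_tbl <- counts |>
    inner_join(lib, by = "sample") |>
    mutate(cpm = 1e6 * .data$count / .data$lib)
  wide <- cpm_tbl |>
    select("feature_id", "sample", "cpm") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "cpm",
                       values_fill = 0)
  s1 <- design$sample[design$condition == conds[1]]
  s2 <- design$sample[design$condition == conds[2]]
  cpm1 <- as.matrix(wide[, s1, drop = FALSE])
  cpm2 <- as.matrix(wide[, s2, drop = FALSE])
  l1 <- log2(cpm1 + 0.5); l2 <- log2(cpm2 + 0.5)

  p <- if (is.null(test_fn)) {
    .row_t_test(l1, l2)
  } else {
    purrr::map_dbl(seq_len(nrow(wide)), ~ test_fn(l1[.x, ], l2[.x, ]))
  }
  m1 <- rowMeans(cpm1); m2 <- rowMeans(cpm2)
  tbl <- tibble(
    feature_id = wide$feature_id,
    mean_cpm_1 = m1, mean_cpm_2 = m2,
    log2fc = log2((m2 + 0.5) / (m1 + 0.5)),
    p_value = p,
    adj_p = bh_adjust(p)
  ) |>
    mutate(de = abs(.data$log2fc) >= log2(fc_threshold) & .data$adj_p < alpha)
  structure(
    list(table = tbl, level = level, conditions = conds,
         fc_threshold = fc_threshold, alpha = alpha),
    class = "de_result"
  )
}

#' Build a DE result from precomputed statistics
#'
#' Accepts externally computed per-feature fold changes and p-values (e.g. a
#' negative-binomial/limma analysis exported as TSV) and applies the same
#' joint thresholds as [de_call()].
#'
#' @param stats Tibble `feature_id`, `log2fc`, and either `adj_p` or
#'   `p_value` (in the latter case [bh_adjust()] is applied).
#' @inheritParams de_call
#' @return A `de_result`.
#' @export
de_from_stats <- function(stats, level = c("gene", "transcript"),
                          fc_threshold = 1.5, alpha = 0.05) {
  level <- match.arg(level)
  stats <- as_tibble(stats)
  stopifnot(all(c("feature_id", "log2fc") %in% names(stats)))
  if (!"adj_p" %in% names(stats)) {
    stopifnot("p_value" %in% names(stats))
    stats$adj_p <- bh_adjust(stats$p_value)
  }
  tbl <- stats |>
    mutate(de = abs(.data$log2fc) >= log2(fc_threshold) & .data$adj_p < alpha)
  structure(
    list(table = tbl, level = level, conditions = NULL,
         fc_threshold = fc_threshold, alpha = alpha),
    class = "de_result"
  )
}

#' @export
print.de_result <- function(x, ...) {
  cat("<de_result> level=", x$level, ": ", sum(x$table$de), " / ",
      nrow(x$table), " features DE (|FC| >= ", x$fc_threshold,
      ", adj p < ", x$alpha, ")\n", sep = "")
  invisible(x)
}

#' @rdname tidy-unionexon
#' @export
tidy.de_result <- function(x, ...) x$table

#' @rdname tidy-unionexon
#' @export
glance.de_result <- function(x, ...) {
  tibble(level = x$level, n_features = nrow(x$table), n_de = sum(x$table$de),
         fc_threshold = x$fc_threshold, alpha = x$alpha)
}

#' Intersect gene-level and transcript-level DE gene sets
#'
#' Groups DE transcripts to their genes (the `DE_Tx_Gene` list), takes the
#' gene-level DE list (`DE_Gene_Gene`), and reports the intersection and both
#' set differences. Genes DE only through an isoform -- e.g. a minor-isoform
#' change or an isoform switch whose directions cancel at the gene level --
#' appear uniquely in `DE_Tx_Gene`.
#'
#' @param gene_de A `de_result` at gene level (feature ids are gene ids).
#' @param tx_de A `de_result` at transcript level (feature ids are
#'   transcript ids).
#' @param ann A `tx_annotation` mapping transcripts to genes.
#' @return A list of class `de_set_comparison`: `sets` (tibble `gene_id`,
#'   `in_gene_level`, `in_tx_level`, `category`) and `sizes` (tibble
#'   `both`, `gene_only`, `tx_only`).
#' @export
intersect_de_sets <- function(gene_de, tx_de, ann) {
  stopifnot(inherits(gene_de, "de_result"), inherits(tx_de, "de_result"),
            inherits(ann, "tx_annotation"))
  de_gene_gene <- gene_de$table$feature_id[gene_de$table$de]
  de_tx <- tx_de$table$feature_id[tx_de$table$de]
  tx2gene <- ann$transcripts |> select("transcript_id", "gene_id")
  de_tx_gene <- tx2gene$gene_id[tx2gene$transcript_id %in% de_tx] |> unique()
  all_genes <- union(de_gene_gene, de_tx_gene)
  sets <- tibble(
    gene_id = all_genes,
    in_gene_level = all_genes %in% de_gene_gene,
    in_tx_level = all_genes %in% de_tx_gene
  ) |>
    mutate(category = case_when(
      .data$in_gene_level & .data$in_tx_level ~ "both",
      .data$in_gene_level ~ "gene_only",
      TRUE ~ "tx_only"
    ))
  sizes <- tibble(
    both = sum(sets$category == "both"),
    gene_only = sum(sets$category == "gene_only"),
    tx_only = sum(sets$category == "tx_only")
  )
  structure(list(sets = sets, sizes = sizes), class = "de_set_comparison")
}

#' @export
print.de_set_comparison <- function(x, ...) {
  cat("<de_set_comparison> both=", x$sizes$both,
      " gene_only=", x$sizes$gene_only,
      " tx_only=", x$sizes$tx_only, "\n", sep = "")
  invisible(x)
}
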