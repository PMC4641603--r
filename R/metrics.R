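#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count / ((length_bp / 1000) * (total_reads / 1e6))`. With a 5 kb
#' feature and a 1-million-read library, a count of 32 gives 6.4 RPKM.
#'
#' @param count Read (or fragment) counts; may be fractional.
#' @param length_bp Feature length in bp (>= 1).
#' @param total_reads Per-sample total mapped reads (>= 1).
#' @return Numeric vector of RPKM values.
#' @export
rpkm <- function(count, length_bp, total_reads) {
  if (any(length_bp < 1) || any(total_reads < 1)) {
    abort("length_bp and total_reads must be >= 1")
  }
  count / ((length_bp / 1000) * (total_reads / 1e6))
}

# resolve the per-sample denominator N: method-specific library size by
# default, or a shared value for cross-method comparability
.resolve_total_reads <- function(counts, total_reads) {
  if (is.null(total_reads)) {
    counts |>
      group_by(.data$sample) |>
      summarise(total_reads = sum(.data$count), .groups = "drop")
  } else if (is.data.frame(total_reads)) {
    as_tibble(total_reads)
  } else if (!is.null(names(total_reads))) {
    tibble(sample = names(total_reads), total_reads = unname(total_reads))
  } else {
    stopifnot(length(total_reads) == 1)
    counts |> distinct(.data$sample) |> mutate(total_reads = total_reads)
  }
}

#' Gene RPKM over union-exon length
#'
#' The two union-length gene RPKM variants: `fc_rpkm` uses the reads counted
#' against union exons by the partial-overlap counter; `rsem_rpkm` uses the
#' per-gene sums of EM expected counts. Both divide by the total length of
#' the gene's union exons.
#'
#' @param counts A tibble `gene_id`, `sample`, `count` (e.g.
#'   `tidy(count_union(...))` or [gene_counts_from_isoforms()] with its
#'   `rsem_count` column renamed to `count`).
#' @param ann A `tx_annotation` supplying `union_length_bp`.
#' @param source `"fc"` or `"rsem"`; recorded as the mode label `fc_rpkm` or
#'   `rsem_rpkm`.
#' @param total_reads Per-sample denominator N. Default (`NULL`): the sum of
#'   the supplied counts per sample (method-specific library size). Pass a
#'   single number, named vector, or `tibble(sample, total_reads)` to share
#'   one N across methods.
#' @return An expression table: tibble `feature_id`, `sample`, `value`,
#'   `mode`, `length_bp`, `total_reads`.
#' @export
gene_rpkm_union <- function(counts, ann, source = c("fc", "rsem"),
                            total_reads = NULL) {
  source <- match.arg(source)
  stopifnot(inherits(ann, "tx_annotation"))
  counts <- as_tibble(counts)
  stopifnot(all(c("gene_id", "sample", "count") %in% names(counts)))
  n_tbl <- .resolve_total_reads(counts, total_reads)
  counts |>
    inner_join(ann$genes |> select("gene_id", "union_length_bp"), by = "gene_id") |>
    inner_join(n_tbl, by = "sample") |>
    mutate(
      value = rpkm(.data$count, .data$union_length_bp, .data$total_reads),
      mode = paste0(source, "_rpkm")
    ) |>
    select(feature_id = "gene_id", "sample", "value", "mode",
           length_bp = "union_length_bp", "total_reads")
}

#' Per-transcript RPKM
#'
#' RPKM of each isoform from its expected count and its own length.
#'
#' @param fit An `isoform_fit`, or a tibble `transcript_id`, `gene_id`,
#'   `sample`, `expected_count`, `length_bp`.
#' @param total_reads As in [gene_rpkm_union()]; default is the per-sample
#'   sum of expected counts.
#' @param use_eff_length If `TRUE`, divide by the effective length instead of
#'   the plain transcript length (default `FALSE`: the density argument
#'   divides by transcript length).
#' @return A tibble `feature_id` (transcript), `gene_id`, `sample`, `value`,
#'   `mode = "tx_rpkm"`, `length_bp`, `total_reads`.
#' @export
transcript_rpkm <- function(fit, total_reads = NULL, use_eff_length = FALSE) {
  est <- if (inherits(fit, "isoform_fit")) fit$estimates else as_tibble(fit)
  counts <- est |> rename(count = "expected_count")
  n_tbl <- .resolve_total_reads(counts, total_reads)
  len <- if (use_eff_length && "eff_length" %in% names(counts)) {
    counts$eff_length
  } else {
    counts$length_bp
  }
  counts |>
    mutate(len_used = pmax(1, len)) |>
    inner_join(n_tbl, by = "sample") |>
    mutate(
      value = rpkm(.data$count, .data$len_used, .data$total_reads),
      mode = "tx_rpkm"
    ) |>
    select(feature_id = "transcript_id", "gene_id", "sample", "value", "mode",
           length_bp = "len_used", "total_reads")
}

#' Gene RPKM as the sum of transcript RPKMs
#'
#' The transcript-based gene expression: the RPKM of each isoform is computed
#' first and the gene RPKM is the sum over its isoforms (mode
#' `rsem_txSum_rpkm`). With isoform RPKMs of 2 and 6, the gene is 8 RPKM.
#'
#' @param tx_table A [transcript_rpkm()] result (tibble with `feature_id`,
#'   `gene_id`, `sample`, `value`).
#' @return A tibble `feature_id` (gene), `sample`, `value`,
#'   `mode = "rsem_txSum_rpkm"`.
#' @export
gene_rpkm_txsum <- function(tx_table) {
  tx_table <- as_tibble(tx_table)
  stopifnot(all(c("gene_id", "sample", "value") %in% names(tx_table)))
  tx_table |>
    group_by(.data$gene_id, .data$sample) |>
    summarise(value = sum(.data$value), .groups = "drop") |>
    mutate(mode = "rsem_txSum_rpkm") |>
    select(feature_id = "gene_id", "sample", "value", "mode")
}

#' Transcripts per million
#'
#' Length-normalized read rates rescaled to sum to one million within each
#' sample: `rate = count / length`, `TPM = 1e6 * rate / sum(rate)`. The mean
#' TPM is therefore always `1e6 / n_features` (50 for 20,000 transcripts),
#' whatever the library -- the invariant-average property that distinguishes
#' TPM from RPKM. Within a sample TPM is proportional to RPKM.
#'
#' @param counts A tibble `feature_id`, `sample`, `count`.
#' @param lengths A tibble `feature_id`, `length_bp` (plain or effective
#'   lengths; use the same convention as the counts' source).
#' @return A tibble `feature_id`, `sample`, `value`, `mode = "tpm"`,
#'   `length_bp`.
#' @export
tpm <- function(counts, lengths) {
  counts <- as_tibble(counts)
  lengths <- as_tibble(lengths)
  stopifnot(
    all(c("feature_id", "sample", "count") %in% names(counts)),
    all(c("feature_id", "length_bp") %in% names(lengths))
  )
  if (any(lengths$length_bp < 1)) abort("lengths must be >= 1")
  counts |>
    inner_join(lengths, by = "feature_id") |>
    group_by(.data$sample) |>
    mutate(
      rate = .data$count / .data$length_bp,
      value = 1e6 * .data$rate / sum(.data$rate),
      mode = "tpm"
    ) |>
    ungroup() |>
    select("feature_id", "sample", "value", "mode", "length_bp")
}

#' Shifted log2 transform for expression values
#'
#' `log2(value + pseudo)`; a pseudo-count of 0.5 keeps zero-expression
#' features finite (0 maps to -1). Used for the scatter-plot axes.
#'
#' @param values Non-negative numeric vector.
#' @param pseudo Pseudo-count added before the log (default 0.5).
#' @return `log2(values + pseudo)`.
#' @export
log_shift <- function(values, pseudo = 0.5) {
  log2(values + pseudo)
}
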