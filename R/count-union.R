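# strand compatibility of a read with a feature under a library protocol:
# reverse-stranded libraries yield reads antisense to the transcript
.strand_compatible <- function(read_strand, feature_strand, strand_mode) {
  switch(strand_mode,
    reverse = read_strand == .flip_strand(feature_strand),
    forward = read_strand == feature_strand,
    unstranded = rep(TRUE, length(read_strand)),
    abort("strand_mode must be 'reverse', 'forward' or 'unstranded'")
  )
}

# per (read, gene) total overlap in bp between read blocks and union exons,
# restricted to strand-compatible genes
.read_gene_overlap <- function(reads, ann, strand_mode) {
  ue <- ann$union_exons
  known <- reads$chrom %in% unique(ue$chrom)
  if (!all(known)) {
    warn(paste0(sum(!known), " read block(s) on chromosomes absent from the annotation"))
  }
  r_ir <- IRanges::IRanges(reads$start + 1L, reads$end)
  u_ir <- IRanges::IRanges(ue$start + 1L, ue$end)
  hits <- IRanges::findOverlaps(r_ir, u_ir)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  keep <- reads$chrom[qi] == ue$chrom[si] &
    .strand_compatible(reads$strand[qi], ue$strand[si], strand_mode)
  qi <- qi[keep]; si <- si[keep]
  ov <- pmin(reads$end[qi], ue$end[si]) - pmax(reads$start[qi], ue$start[si])
  tibble(
    read_id = reads$read_id[qi],
    sample = reads$sample[qi],
    gene_id = ue$gene_id[si],
    overlap = ov
  ) |>
    group_by(.data$read_id, .data$sample, .data$gene_id) |>
    summarise(overlap = sum(.data$overlap), .groups = "drop")
}

#' Assign reads to genes against union exons
#'
#' The union-exon counting rule: a read's overlap with a gene is the total
#' number of its aligned bases (summed over blocks) falling inside the gene's
#' union exons, counted only for strand-compatible genes. A gene qualifies
#' when the overlap reaches `min_overlap_bp`. A read with exactly one
#' qualifying gene is assigned to it; with two or more it is `AMBIGUOUS`
#' (excluded from counting, since there is no way to tell which gene it came
#' from); with none it is `NO_FEATURE`.
#'
#' @param reads A block tibble (columns `read_id`, `sample`, `chrom`,
#'   `strand`, `start`, `end`), e.g. from [simulate_reads()] or
#'   [read_reads_bed12()].
#' @param ann A `tx_annotation`.
#' @param min_overlap_bp Minimum qualifying overlap in bp (default 18; a
#'   17 bp overlap is not counted, an 18 bp overlap is).
#' @param strand_mode `"reverse"` (default), `"forward"`, or `"unstranded"`.
#' @return A tibble with one row per read: `read_id`, `sample`, `gene_id`
#'   (`NA` unless assigned), `status` (`assigned`, `ambiguous`,
#'   `no_feature`).
#' @export
assign_read_union <- function(reads, ann, min_overlap_bp = 18L,
                              strand_mode = c("reverse", "forward", "unstranded")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(ann, "tx_annotation"), min_overlap_bp >= 1)
  reads <- as_tibble(reads)
  all_reads <- reads |> distinct(.data$read_id, .data$sample)
  if (nrow(all_reads) == 0) {
    return(tibble(read_id = character(0), sample = character(0),
                  gene_id = character(0), status = character(0)))
  }
  qualifying <- .read_gene_overlap(reads, ann, strand_mode) |>
    filter(.data$overlap >= min_overlap_bp)
  per_read <- qualifying |>
    group_by(.data$read_id, .data$sample) |>
    summarise(
      n_genes = dplyr::n(),
      gene_id = .data$gene_id[1],
      .groups = "drop"
    ) |>
    mutate(
      status = if_else(.data$n_genes > 1L, "ambiguous", "assigned"),
      gene_id = if_else(.data$n_genes > 1L, NA_character_, .data$gene_id)
    )
  all_reads |>
    left_join(per_read |> select(-"n_genes"), by = c("read_id", "sample")) |>
    mutate(status = if_else(is.na(.data$status), "no_feature", .data$status))
}

#' Count reads per gene against union exons
#'
#' Runs [assign_read_union()] and tabulates per-gene fragment counts per
#' sample, together with the assignment summary (counts and percentages of
#' assigned, ambiguous and no-feature reads).
#'
#' @inheritParams assign_read_union
#' @return A list of class `union_counts`:
#'   \describe{
#'     \item{counts}{tibble `gene_id`, `sample`, `count`, complete over all
#'       genes of the annotation (zero-filled);}
#'     \item{summary}{tibble per sample with `total`, `assigned`,
#'       `ambiguous`, `no_feature` and the corresponding percentages;}
#'     \item{assignments}{the per-read assignment tibble.}
#'   }
#' @export
count_union <- function(reads, ann, min_overlap_bp = 18L,
                        strand_mode = c("reverse", "forward", "unstranded")) {
  strand_mode <- match.arg(strand_mode)
  asg <- assign_read_union(reads, ann, min_overlap_bp, strand_mode)
  samples <- unique(asg$sample)
  if (length(samples) == 0) samples <- character(0)
  counts <- asg |>
    filter(.data$status == "assigned") |>
    count(.data$gene_id, .data$sample, name = "count")
  grid <- tidyr::expand_grid(gene_id = ann$genes$gene_id, sample = samples)
  counts <- grid |>
    left_join(counts, by = c("gene_id", "sample")) |>
    mutate(count = as.integer(tidyr::replace_na(.data$count, 0L)))
  summary <- asg |>
    count(.data$sample, .data$status) |>
    tidyr::pivot_wider(names_from = "status", values_from = "n", values_fill = 0L)
  for (col in c("assigned", "ambiguous", "no_feature")) {
    if (!col %in% names(summary)) summary[[col]] <- 0L
  }
  summary <- summary |>
    mutate(
      total = .data$assigned + .data$ambiguous + .data$no_feature,
      pct_assigned = 100 * .data$assigned / pmax(1L, .data$total),
      pct_ambiguous = 100 * .data$ambiguous / pmax(1L, .data$total),
      pct_no_feature = 100 * .data$no_feature / pmax(1L, .data$total)
    ) |>
    select("sample", "total", "assigned", "ambiguous", "no_feature",
           dplyr::starts_with("pct_"))
  structure(
    list(counts = counts, summary = summary, assignments = asg),
    class = "union_counts"
  )
}

#' @export
print.union_counts <- function(x, ...) {
  cat("<union_counts> ", dplyr::n_distinct(x$counts$gene_id), " genes x ",
      dplyr::n_distinct(x$counts$sample), " sample(s)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname tidy-unionexon
#' @export
tidy.union_counts <- function(x, ...) x$counts

#' @rdname tidy-unionexon
#' @export
glance.union_counts <- function(x, ...) x$summary
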