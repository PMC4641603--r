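#' Merge overlapping or touching genomic intervals
#'
#' Flattens a set of intervals on a single chromosome/strand into the minimal
#' sorted set of disjoint intervals covering the same bases. This is the exon
#' flattening step of the union-exon approach: all overlapping exons of a gene
#' are collapsed into "union exons". Intervals that merely touch (the end of
#' one equals the start of the next in half-open coordinates) are merged, since
#' zero-length gaps are annotation artifacts, not introns.
#'
#' All coordinates are 0-based half-open, so `end - start` is the interval
#' length in bp.
#'
#' @param intervals A data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open). A `strand` column, if present, is carried through; all rows
#'   must share one chromosome and strand.
#' @return A tibble with the same columns, sorted by `start`, rows pairwise
#'   disjoint.
#' @examples
#' merge_intervals(tibble::tibble(
#'   chrom = "chr1", start = c(0, 50), end = c(100, 150)
#' ))
#' @export
merge_intervals <- function(intervals) {
  intervals <- as_tibble(intervals)
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) == 0) {
    return(intervals[0, , drop = FALSE])
  }
  if (length(unique(intervals$chrom)) > 1L) {
    abort("merge_intervals() requires all intervals on a single chromosome")
  }
  if ("strand" %in% names(intervals) && length(unique(intervals$strand)) > 1L) {
    abort("merge_intervals() requires all intervals on a single strand")
  }
  if (any(intervals$start >= intervals$end)) {
    abort("intervals must satisfy start < end (0-based half-open)")
  }
  ir <- IRanges::reduce(IRanges::IRanges(intervals$start + 1L, intervals$end))
  out <- tibble(
    chrom = intervals$chrom[1],
    start = IRanges::start(ir) - 1L,
    end   = IRanges::end(ir)
  )
  if ("strand" %in% names(intervals)) out$strand <- intervals$strand[1]
  out
}

#' Build an annotation from a tidy exon table
#'
#' Constructs the gene/transcript/exon model used throughout the package from
#' one long exon table. Union exons (all exons of a gene flattened into
#' disjoint intervals) and per-gene structural features are computed here, so
#' every downstream step shares a single definition of gene length.
#'
#' @param exons A data frame with one row per exon and columns `gene_id`,
#'   `transcript_id`, `chrom`, `strand` (`"+"` or `"-"`), `start`, `end`
#'   (0-based half-open).
#' @return A `tx_annotation` object: a list of tibbles
#'   \describe{
#'     \item{exons}{the validated input, sorted by transcript and start;}
#'     \item{transcripts}{`transcript_id`, `gene_id`, `chrom`, `strand`,
#'       `length_bp` (sum of exon lengths), `n_exons`;}
#'     \item{union_exons}{one row per union exon with `gene_id`;}
#'     \item{genes}{`gene_id`, `chrom`, `strand`, `union_length_bp`,
#'       `n_union_exons`, `n_transcripts`.}
#'   }
#' @export
annotation <- function(exons) {
  exons <- as_tibble(exons)
  needed <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  missing_cols <- setdiff(needed, names(exons))
  if (length(missing_cols) > 0) {
    abort(paste0("exon table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  exons <- exons |>
    select(dplyr::all_of(needed)) |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
    arrange(.data$gene_id, .data$transcript_id, .data$start)
  if (any(exons$start >= exons$end)) {
    abort("exons must satisfy start < end (0-based half-open)")
  }
  if (!all(exons$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-' for every exon")
  }
  per_tx_chrom <- exons |>
    group_by(.data$transcript_id) |>
    summarise(
      n_chrom = dplyr::n_distinct(.data$chrom),
      n_strand = dplyr::n_distinct(.data$strand),
      n_gene = dplyr::n_distinct(.data$gene_id),
      .groups = "drop"
    )
  if (any(per_tx_chrom$n_chrom > 1 | per_tx_chrom$n_strand > 1)) {
    abort("every transcript must lie on a single chromosome and strand")
  }
  if (any(per_tx_chrom$n_gene > 1)) {
    abort("a transcript_id may belong to only one gene_id")
  }

  transcripts <- exons |>
    group_by(.data$transcript_id, .data$gene_id, .data$chrom, .data$strand) |>
    summarise(
      length_bp = sum(.data$end - .data$start),
      n_exons = dplyr::n(),
      .groups = "drop"
    ) |>
    arrange(.data$gene_id, .data$transcript_id)

  union_exons <- exons |>
    group_by(.data$gene_id) |>
    dplyr::group_modify(~ merge_intervals(.x[, c("chrom", "start", "end", "strand")])) |>
    ungroup() |>
    select("gene_id", "chrom", "start", "end", "strand")

  genes <- union_exons |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(
      union_length_bp = sum(.data$end - .data$start),
      n_union_exons = dplyr::n(),
      .groups = "drop"
    ) |>
    left_join(
      transcripts |> count(.data$gene_id, name = "n_transcripts"),
      by = "gene_id"
    ) |>
    arrange(.data$gene_id)

  structure(
    list(
      exons = exons,
      transcripts = transcripts,
      union_exons = union_exons,
      genes = genes
    ),
    class = "tx_annotation"
  )
}

#' @export
print.tx_annotation <- function(x, ...) {
  cat(
    "<tx_annotation> ", nrow(x$genes), " genes, ",
    nrow(x$transcripts), " transcripts, ",
    nrow(x$exons), " exons (", nrow(x$union_exons), " union exons)\n",
    sep = ""
  )
  invisible(x)
}

#' Subset an annotation to a set of genes
#'
#' @param ann A `tx_annotation`.
#' @param gene_ids Character vector of gene ids to keep.
#' @return A `tx_annotation` restricted to the given genes.
#' @export
subset_annotation <- function(ann, gene_ids) {
  stopifnot(inherits(ann, "tx_annotation"))
  annotation(ann$exons |> filter(.data$gene_id %in% gene_ids))
}

#' Read a GENCODE-style GTF into an annotation
#'
#' Parses the `exon` features of a GTF file (GENCODE attribute dialect:
#' `gene_id` and `transcript_id` attributes) and builds the package's
#' gene/transcript/exon model. GTF's 1-based inclusive coordinates are
#' converted to the 0-based half-open convention used internally, so a GTF
#' exon `1 100` becomes the interval `[0, 100)` of length 100.
#'
#' @param path Path to a GTF file.
#' @return A [annotation()] object.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) abort(paste0("GTF file not found: ", path))
  lines <- readr::read_lines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfields <- stringr::str_count(lines[body], stringr::fixed("\t")) + 1L
  if (any(nfields < 9L)) {
    bad <- which(body)[which(nfields < 9L)[1]]
    abort(paste0("malformed GTF line ", bad, ": expected 9 tab-separated fields"))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) abort("GTF contains no exon features")
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id)) {
    abort("GTF exon feature without a transcript_id attribute")
  }
  if (is.null(gr$gene_id) || anyNA(gr$gene_id)) {
    abort("GTF exon feature without a gene_id attribute")
  }
  df <- as.data.frame(gr)
  annotation(tibble(
    gene_id = df$gene_id,
    transcript_id = df$transcript_id,
    chrom = as.character(df$seqnames),
    strand = as.character(df$strand),
    start = df$start - 1L,
    end = df$end
  ))
}

#' Write union exons as BED6 and gene features as TSV
#'
#' Exports the flattened gene model: one BED6 record per union exon (name =
#' gene id, score = 0) and a gene feature table with the per-gene structural
#' summaries. BED uses 0-based half-open coordinates, identical to the
#' internal convention.
#'
#' @param ann A `tx_annotation`.
#' @param bed_path,tsv_path Output paths; either may be `NULL` to skip.
#' @return `ann`, invisibly.
#' @export
write_annotation_tables <- function(ann, bed_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(ann, "tx_annotation"))
  if (!is.null(bed_path)) {
    ann$union_exons |>
      mutate(name = .data$gene_id, score = 0L) |>
      select("chrom", "start", "end", "name", "score", "strand") |>
      readr::write_tsv(bed_path, col_names = FALSE)
  }
  if (!is.null(tsv_path)) {
    readr::write_tsv(ann$genes, tsv_path)
  }
  invisible(ann)
}

#' Write an annotation as GTF
#'
#' Emits `exon` features with `gene_id` and `transcript_id` attributes,
#' converting back to GTF's 1-based inclusive coordinates. Round-trips with
#' [read_gtf()].
#'
#' @param ann A `tx_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  stopifnot(inherits(ann, "tx_annotation"))
  e <- ann$exons
  attrs <- sprintf(
    'gene_id "%s"; transcript_id "%s";', e$gene_id, e$transcript_id
  )
  readr::write_lines(
    paste(e$chrom, "unionexon", "exon", e$start + 1L, e$end, ".", e$strand, ".",
          attrs, sep = "\t"),
    path
  )
  invisible(path)
}

#' Gene filtering configuration
#'
#' Bundles the four exclusion rules applied before comparing quantification
#' approaches: mitochondrial genes, same-strand overlapping gene pairs, genes
#' without appreciable expression, and genes with short union-exon models.
#'
#' @param min_count Keep a gene only if its count reaches `min_count` in at
#'   least one sample (default 100; a gene whose counts are below 100 in every
#'   sample is dropped).
#' @param min_union_length_bp Minimum total union-exon length in bp
#'   (default 500; a 499 bp gene is dropped, a 500 bp gene kept).
#' @param mito_chrom_names Chromosome names treated as mitochondrial.
#' @param exclude_same_strand_overlap If `TRUE`, any two genes whose union
#'   exons overlap by at least 1 bp on the same strand are both removed.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_count = 100L,
                          min_union_length_bp = 500L,
                          mito_chrom_names = c("chrM", "MT"),
                          exclude_same_strand_overlap = TRUE) {
  stopifnot(min_count >= 0, min_union_length_bp >= 0)
  structure(
    list(
      min_count = as.integer(min_count),
      min_union_length_bp = as.integer(min_union_length_bp),
      mito_chrom_names = mito_chrom_names,
      exclude_same_strand_overlap = isTRUE(exclude_same_strand_overlap)
    ),
    class = "filter_config"
  )
}

#' Filter genes before quantification comparison
#'
#' Applies, in fixed precedence, the exclusion rules of [filter_config()]:
#' (a) mitochondrial genes, (b) same-strand union-exon overlap (both members
#' of an overlapping pair are removed), (c) counts below `min_count` in every
#' sample, (d) union-exon length below `min_union_length_bp`. Each gene is
#' tallied under the first rule that removes it, so the tallies sum to the
#' number of genes removed.
#'
#' @param ann A `tx_annotation`.
#' @param counts A data frame with columns `gene_id`, `sample`, `count`
#'   covering every gene in `ann` (extra genes are ignored).
#' @param cfg A [filter_config()].
#' @return A list with `annotation` (the surviving `tx_annotation`) and
#'   `removals`, a tibble with columns `rule` (`mito`, `strand_overlap`,
#'   `low_count`, `short_union`) and `n_removed`.
#' @export
filter_genes <- function(ann, counts, cfg = filter_config()) {
  stopifnot(inherits(ann, "tx_annotation"), inherits(cfg, "filter_config"))
  counts <- as_tibble(counts)
  stopifnot(all(c("gene_id", "sample", "count") %in% names(counts)))
  missing_genes <- setdiff(ann$genes$gene_id, counts$gene_id)
  if (length(missing_genes) > 0) {
    abort(paste0(
      "counts table missing gene_id(s): ",
      paste(head(missing_genes, 5), collapse = ", "),
      if (length(missing_genes) > 5) ", ..."
    ))
  }

  removed <- character(0)
  tally <- c(mito = 0L, strand_overlap = 0L, low_count = 0L, short_union = 0L)
  remaining <- ann$genes

  # (a) mitochondrial
  hit <- remaining$gene_id[remaining$chrom %in% cfg$mito_chrom_names]
  tally["mito"] <- length(hit)
  removed <- c(removed, hit)
  remaining <- remaining |> filter(!.data$gene_id %in% hit)

  # (b) same-strand union-exon overlap (>= 1 bp); both members removed
  if (cfg$exclude_same_strand_overlap && nrow(remaining) > 1) {
    ue <- ann$union_exons |> filter(.data$gene_id %in% remaining$gene_id)
    key <- paste(ue$chrom, ue$strand)
    ir <- IRanges::IRanges(ue$start + 1L, ue$end)
    overlapping <- unique(unlist(lapply(unique(key), function(k) {
      idx <- which(key == k)
      if (length(idx) < 2) return(character(0))
      h <- IRanges::findOverlaps(ir[idx], ir[idx])
      qg <- ue$gene_id[idx][S4Vectors::queryHits(h)]
      sg <- ue$gene_id[idx][S4Vectors::subjectHits(h)]
      unique(c(qg[qg != sg], sg[qg != sg]))
    })))
    tally["strand_overlap"] <- length(overlapping)
    removed <- c(removed, overlapping)
    remaining <- remaining |> filter(!.data$gene_id %in% overlapping)
  }

  # (c) no appreciable expression: below min_count in every sample
  max_counts <- counts |>
    group_by(.data$gene_id) |>
    summarise(max_count = max(.data$count), .groups = "drop")
  low <- remaining |>
    left_join(max_counts, by = "gene_id") |>
    filter(.data$max_count < cfg$min_count) |>
    pull("gene_id")
  tally["low_count"] <- length(low)
  removed <- c(removed, low)
  remaining <- remaining |> filter(!.data$gene_id %in% low)

  # (d) short union-exon model
  short <- remaining$gene_id[remaining$union_length_bp < cfg$min_union_length_bp]
  tally["short_union"] <- length(short)
  remaining <- remaining |> filter(!.data$gene_id %in% short)

  list(
    annotation = subset_annotation(ann, remaining$gene_id),
    removals = tibble(rule = names(tally), n_removed = unname(tally))
  )
}

#' Structural features used for ratio binning
#'
#' Returns, per gene, the two structural covariates along which the
#' transcript-sum/union RPKM ratio is summarized: the number of union exons
#' and the number of annotated transcript isoforms.
#'
#' @param ann A `tx_annotation`.
#' @return A tibble with `gene_id`, `n_union_exons`, `n_transcripts`.
#' @export
structural_features <- function(ann) {
  stopifnot(inherits(ann, "tx_annotation"))
  ann$genes |> select("gene_id", "n_union_exons", "n_transcripts")
}
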