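test_that("merge_intervals flattens overlapping, touching and disjoint exons", {
  empty <- merge_intervals(tibble::tibble(chrom = character(0),
                                          start = integer(0), end = integer(0)))
  expect_equal(nrow(empty), 0)

  # two isoforms over a 2/1/2 kb exon chain flatten to three union exons
  iv <- tibble::tibble(
    chrom = "chr1",
    start = c(0L, 3000L, 5000L, 0L, 5000L),
    end   = c(2000L, 4000L, 7000L, 2000L, 7000L)
  )
  m <- merge_intervals(iv)
  expect_equal(m$start, c(0L, 3000L, 5000L))
  expect_equal(m$end - m$start, c(2000L, 1000L, 2000L))

  ov <- merge_intervals(tibble::tibble(chrom = "c", start = c(0L, 50L),
                                       end = c(100L, 150L)))
  expect_equal(ov$start, 0L)
  expect_equal(ov$end, 150L)

  touching <- merge_intervals(tibble::tibble(chrom = "c", start = c(0L, 100L),
                                             end = c(100L, 200L)))
  expect_equal(nrow(touching), 1)

  expect_error(
    merge_intervals(tibble::tibble(chrom = c("a", "b"), start = c(0L, 0L),
                                   end = c(1L, 1L))),
    "single chromosome"
  )
})

test_that("merge_intervals is idempotent and preserves the covered base set", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(1:8, 1)
    s <- sample(0:300, n)
    iv <- tibble::tibble(chrom = "c", start = s, end = s + sample(1:80, n, replace = TRUE))
    m <- merge_intervals(iv)
    expect_true(all(m$start[-1] > m$end[-nrow(m)] | nrow(m) == 1))
    expect_identical(merge_intervals(m), m)
    expect_equal(sum(m$end - m$start), brute_union_length(iv$start, iv$end))
  }
})

test_that("read_gtf round-trips a toy annotation with coordinate conversion", {
  path <- write_toy_gtf(c(
    gtf_line("chr1", 1, 100, "+", "GA", "GA.t1"),
    gtf_line("chr1", 201, 300, "+", "GA", "GA.t1"),
    gtf_line("chr1", 401, 500, "+", "GA", "GA.t1"),
    gtf_line("chr1", 1, 100, "+", "GA", "GA.t2"),
    gtf_line("chr1", 401, 500, "+", "GA", "GA.t2"),
    gtf_line("chr1", 451, 520, "+", "GA", "GA.t2")
  ))
  ann <- read_gtf(path)
  expect_equal(nrow(ann$genes), 1)
  expect_equal(nrow(ann$transcripts), 2)
  # 1-based [1, 100] becomes half-open (0, 100), length 100
  e1 <- ann$exons[1, ]
  expect_equal(e1$start, 0L)
  expect_equal(e1$end, 100L)

  # a non-exon feature line is ignored
  path2 <- write_toy_gtf(c(
    gtf_line("chr1", 1, 500, "+", "GA", "GA.t1", feature = "transcript"),
    gtf_line("chr1", 1, 100, "+", "GA", "GA.t1")
  ))
  expect_equal(nrow(read_gtf(path2)$exons), 1)

  expect_error(read_gtf(write_toy_gtf("chr1\tonly\tthree")), "malformed GTF line 1")
})

test_that("genes on opposite strands at one locus stay separate", {
  path <- write_toy_gtf(c(
    gtf_line("chr1", 1, 1000, "+", "GP", "GP.t1"),
    gtf_line("chr1", 2001, 3000, "+", "GP", "GP.t1"),
    gtf_line("chr1", 1, 1000, "-", "GM", "GM.t1"),
    gtf_line("chr1", 2001, 3000, "-", "GM", "GM.t1")
  ))
  ann <- read_gtf(path)
  expect_equal(sort(ann$genes$gene_id), c("GM", "GP"))
  expect_equal(ann$genes$union_length_bp, c(2000L, 2000L))
})

test_that("annotation derives union length and structural features", {
  ann <- two_isoform_ann()
  expect_equal(ann$genes$union_length_bp, 5000L)
  sf <- structural_features(ann)
  expect_equal(sf$n_union_exons, 3L)
  expect_equal(sf$n_transcripts, 2L)

  single <- annotation(tibble::tibble(
    gene_id = "S", transcript_id = "S.t1", chrom = "c", strand = "+",
    start = 0L, end = 800L
  ))
  expect_equal(structural_features(single)$n_union_exons, 1L)
  expect_equal(structural_features(single)$n_transcripts, 1L)
  # single-transcript gene: union length equals transcript length
  expect_equal(single$genes$union_length_bp, single$transcripts$length_bp)

  # three isoforms flattening to two union exons
  ann32 <- annotation(tibble::tribble(
    ~gene_id, ~transcript_id, ~chrom, ~strand, ~start, ~end,
    "R", "R.t1", "c", "+",    0L,  400L,
    "R", "R.t1", "c", "+", 1000L, 1100L,
    "R", "R.t2", "c", "+",  100L,  450L,
    "R", "R.t3", "c", "+",    0L,  450L,
    "R", "R.t3", "c", "+", 1000L, 1100L
  ))
  sf32 <- structural_features(ann32)
  expect_equal(sf32$n_union_exons, 2L)
  expect_equal(sf32$n_transcripts, 3L)
})

test_that("union length matches transcript length for all single-isoform genes", {
  ann <- simulate_annotation(25, seed = 3,
                             isoform_count_sampler = function(n) rep(1L, n))
  expect_equal(ann$genes$union_length_bp,
               ann$transcripts$length_bp[match(ann$genes$gene_id,
                                               ann$transcripts$gene_id)])
})

test_that("annotation writers round-trip and export the flattened model", {
  ann <- two_isoform_ann()
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann, gtf)
  back <- read_gtf(gtf)
  expect_equal(back$exons, ann$exons)
  expect_equal(back$genes, ann$genes)

  bed <- withr::local_tempfile(fileext = ".bed")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_tables(ann, bed_path = bed, tsv_path = tsv)
  bed_df <- readr::read_tsv(bed, col_names = c("chrom", "start", "end",
                                               "name", "score", "strand"),
                            show_col_types = FALSE)
  expect_equal(nrow(bed_df), 3)           # one record per union exon
  expect_equal(unique(bed_df$name), "G1") # name column is the gene id
  expect_equal(sum(bed_df$end - bed_df$start), 5000)
  gene_tbl <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(gene_tbl$union_length_bp, 5000)
  expect_equal(gene_tbl$n_transcripts, 2)
})

test_that("filter_genes applies the four exclusion rules with fixed precedence", {
  exons <- dplyr::bind_rows(
    tibble::tibble(gene_id = "gM", transcript_id = "gM.t", chrom = "chrM",
                   strand = "+", start = 0L, end = 600L),
    tibble::tibble(gene_id = "gO1", transcript_id = "gO1.t", chrom = "c1",
                   strand = "+", start = 0L, end = 700L),
    tibble::tibble(gene_id = "gO2", transcript_id = "gO2.t", chrom = "c1",
                   strand = "+", start = 650L, end = 1400L),
    tibble::tibble(gene_id = "gA1", transcript_id = "gA1.t", chrom = "c2",
                   strand = "+", start = 0L, end = 700L),
    tibble::tibble(gene_id = "gA2", transcript_id = "gA2.t", chrom = "c2",
                   strand = "-", start = 650L, end = 1400L),
    tibble::tibble(gene_id = "gLow", transcript_id = "gLow.t", chrom = "c3",
                   strand = "+", start = 0L, end = 600L),
    tibble::tibble(gene_id = "gKeep", transcript_id = "gKeep.t", chrom = "c4",
                   strand = "+", start = 0L, end = 600L),
    tibble::tibble(gene_id = "gShort", transcript_id = "gShort.t", chrom = "c5",
                   strand = "+", start = 0L, end = 499L),
    tibble::tibble(gene_id = "gLen", transcript_id = "gLen.t", chrom = "c6",
                   strand = "+", start = 0L, end = 500L)
  )
  ann <- annotation(exons)
  samples <- paste0("s", 1:4)
  counts <- tidyr::expand_grid(gene_id = ann$genes$gene_id, sample = samples) |>
    dplyr::mutate(count = 150L)
  counts$count[counts$gene_id == "gLow"] <- 99L
  # boundary: reaching 100 in a single sample retains the gene
  counts$count[counts$gene_id == "gKeep"] <- c(99L, 99L, 99L, 100L)

  res <- filter_genes(ann, counts)
  kept <- res$annotation$genes$gene_id
  expect_setequal(kept, c("gA1", "gA2", "gKeep", "gLen"))
  tally <- setNames(res$removals$n_removed, res$removals$rule)
  expect_equal(tally[["mito"]], 1L)
  expect_equal(tally[["strand_overlap"]], 2L)  # both members of the pair
  expect_equal(tally[["low_count"]], 1L)
  expect_equal(tally[["short_union"]], 1L)
  # tallies account for every removed gene exactly once
  expect_equal(sum(res$removals$n_removed),
               nrow(ann$genes) - nrow(res$annotation$genes))

  expect_error(filter_genes(ann, counts[counts$gene_id != "gLen", ]),
               "gLen")
})
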