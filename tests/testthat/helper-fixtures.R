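# Shared fixtures and independent brute-force oracles.

# -- tiny annotations ---------------------------------------------------------

# one gene, two isoforms sharing exon 1 and 3 (fig1-like geometry: 2/1/2 kb)
two_isoform_ann <- function() {
  annotation(tibble::tribble(
    ~gene_id, ~transcript_id, ~chrom, ~strand, ~start, ~end,
    "G1", "G1.t1", "chr1", "+",     0L,  2000L,
    "G1", "G1.t1", "chr1", "+",  3000L,  4000L,
    "G1", "G1.t1", "chr1", "+",  5000L,  7000L,
    "G1", "G1.t2", "chr1", "+",     0L,  2000L,
    "G1", "G1.t2", "chr1", "+",  5000L,  7000L
  ))
}

# gene whose transcript is a chain of many short exons with short introns:
# every read overlaps exons enough to be union-counted, but any read drawn
# from the unspliced span touches an intron and is dropped by the strict rule
ir_stress_ann <- function(n_exons = 12L, exon_len = 60L, intron_len = 40L) {
  starts <- (seq_len(n_exons) - 1L) * (exon_len + intron_len)
  annotation(tibble::tibble(
    gene_id = "GIR", transcript_id = "GIR.t1", chrom = "chrI", strand = "+",
    start = starts, end = starts + exon_len
  ))
}

# write a small GENCODE-dialect GTF and return its path
write_toy_gtf <- function(lines, path = withr::local_tempfile(fileext = ".gtf",
                                                              .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

gtf_line <- function(chrom, start1, end1, strand, gene, tx, feature = "exon") {
  paste(chrom, "test", feature, start1, end1, ".", strand, ".",
        sprintf('gene_id "%s"; transcript_id "%s";', gene, tx),
        sep = "\t")
}

# -- brute-force oracles ------------------------------------------------------

# distinct covered base positions of a set of (start, end) half-open intervals
brute_union_length <- function(start, end) {
  length(unique(unlist(mapply(function(s, e) seq(s, e - 1L), start, end,
                              SIMPLIFY = FALSE))))
}

# per-base union-exon read assignment, re-deriving overlap by set intersection
brute_assign <- function(blocks, ann, min_overlap = 18L, strand_mode = "reverse") {
  read_bases <- unlist(mapply(function(s, e) seq(s, e - 1L),
                              blocks$start, blocks$end, SIMPLIFY = FALSE))
  flip <- c(`+` = "-", `-` = "+")
  hits <- character(0)
  for (g in ann$genes$gene_id) {
    ue <- ann$union_exons[ann$union_exons$gene_id == g, ]
    if (ue$chrom[1] != blocks$chrom[1]) next
    ok <- switch(strand_mode,
      reverse = blocks$strand[1] == flip[[ue$strand[1]]],
      forward = blocks$strand[1] == ue$strand[1],
      unstranded = TRUE
    )
    if (!ok) next
    gene_bases <- unlist(mapply(function(s, e) seq(s, e - 1L),
                                ue$start, ue$end, SIMPLIFY = FALSE))
    if (length(intersect(read_bases, gene_bases)) >= min_overlap) hits <- c(hits, g)
  }
  if (length(hits) == 0) return("NO_FEATURE")
  if (length(hits) > 1) return("AMBIGUOUS")
  hits
}

# explicit min-over-suffix Benjamini-Hochberg
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(o == i)          # ascending rank of p[i]
    suffix <- o[seq(r, m)]
    q[i] <- min(1, min(p[suffix] * m / seq(r, m)))
  }
  q
}

# grid-search maximizer of the two-transcript observed-data log-likelihood;
# classes: list of integer vectors over transcripts 1:2, counts aligned
grid_mle_2tx <- function(class_sets, class_counts, eff_len, step = 1e-5) {
  grid <- seq(0, 1, by = step)
  ll <- rep(0, length(grid))
  for (k in seq_along(class_sets)) {
    dens <- rep(0, length(grid))
    for (t in class_sets[[k]]) {
      th <- if (t == 1) grid else 1 - grid
      dens <- dens + th / eff_len[t]
    }
    ll <- ll + class_counts[k] * log(dens)
  }
  theta1 <- grid[which.max(ll)]
  c(theta1, 1 - theta1)
}

# hand-build a compat_matrix (bypassing read geometry) for EM oracle tests
manual_compat <- function(class_sets, class_counts, tx_ids, gene_ids, eff_len,
                          sample = "S1") {
  class_id <- vapply(class_sets, function(s) paste(sort(tx_ids[s]), collapse = "|"), "")
  structure(list(
    classes = tibble::tibble(sample = sample, class_id = class_id,
                             n_reads = class_counts),
    members = tibble::tibble(
      class_id = rep(class_id, lengths(class_sets)),
      transcript_id = tx_ids[unlist(class_sets)]
    ),
    eff_lengths = tibble::tibble(transcript_id = tx_ids, gene_id = gene_ids,
                                 length_bp = as.integer(eff_len),
                                 eff_length = eff_len),
    summary = tibble::tibble(sample = sample,
                             n_reads = sum(class_counts),
                             n_compatible = sum(class_counts),
                             n_dropped = 0L),
    read_length = 1L
  ), class = "compat_matrix")
}
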