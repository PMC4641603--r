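#' Simulation configuration
#'
#' Settings for the stranded spliced-read simulator. Defaults mirror a typical
#' stranded Illumina protocol: 75 bp reads, reverse-stranded libraries (each
#' read is antisense to its transcript of origin), no intron retention.
#'
#' @param seed Integer seed; every stochastic operation in the simulator is
#'   reproducible under it.
#' @param read_length_bp Read length in bp (default 75).
#' @param paired If `TRUE`, a fragment is simulated and represented as a
#'   single aligned unit whose blocks are the union of both mates' blocks;
#'   counting is at fragment level.
#' @param fragment_length_mean,fragment_length_sd Fragment length model for
#'   paired simulation (normal, clipped to `[read_length_bp, transcript length]`).
#' @param strand_protocol One of `"reverse"` (default; read strand is the
#'   opposite of the transcript strand), `"forward"`, or `"unstranded"`.
#' @param intron_retention_rate Fraction of reads re-drawn uniformly from the
#'   unspliced pre-mRNA span of the gene instead of the mature transcript
#'   (default 0). Such reads carry the truth label `INTRON_RETENTION`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       read_length_bp = 75L,
                       paired = FALSE,
                       fragment_length_mean = 200,
                       fragment_length_sd = 20,
                       strand_protocol = c("reverse", "forward", "unstranded"),
                       intron_retention_rate = 0) {
  strand_protocol <- match.arg(strand_protocol)
  stopifnot(
    read_length_bp >= 1,
    intron_retention_rate >= 0, intron_retention_rate <= 1
  )
  structure(
    list(
      seed = as.integer(seed),
      read_length_bp = as.integer(read_length_bp),
      paired = isTRUE(paired),
      fragment_length_mean = fragment_length_mean,
      fragment_length_sd = fragment_length_sd,
      strand_protocol = strand_protocol,
      intron_retention_rate = intron_retention_rate
    ),
    class = "sim_config"
  )
}

.flip_strand <- function(s) ifelse(s == "+", "-", "+")

# Build one gene's exon table from exon/intron lengths and isoform exon-index
# sets; `offset` is the genomic start of the first exon.
.gene_from_structure <- function(gene_id, exon_lengths, intron_lengths,
                                 isoforms, strand = "+", chrom = "chrS",
                                 offset = 0L) {
  k <- length(exon_lengths)
  stopifnot(length(intron_lengths) == k - 1 || k == 1)
  starts <- offset + cumsum(c(0L, head(exon_lengths, -1) + intron_lengths))
  ends <- starts + exon_lengths
  if (is.null(names(isoforms))) {
    names(isoforms) <- paste0(gene_id, ".t", seq_along(isoforms))
  }
  purrr::imap_dfr(isoforms, function(idx, tx) {
    tibble(
      gene_id = gene_id, transcript_id = tx, chrom = chrom, strand = strand,
      start = starts[idx], end = ends[idx]
    )
  })
}

#' Simulate a multi-isoform gene annotation
#'
#' Generates `n_genes` genes laid out without overlap along one virtual
#' chromosome. Each gene receives an exon chain with lengths drawn from
#' `exon_length_menu` and introns from `intron_length_menu`; its first isoform
#' is the full chain and additional isoforms are random exon subsets, so
#' isoforms of a gene share exons the way annotated transcripts do. The
#' default isoform-count sampler averages about 7 isoforms per gene, the
#' density seen in comprehensive human annotation.
#'
#' @param n_genes Number of genes (>= 1).
#' @param isoform_count_sampler Function `n -> integer vector` giving the
#'   number of isoforms per gene (default `1 + rpois(n, 6)`).
#' @param exon_length_menu,intron_length_menu Integer vectors sampled from
#'   (uniformly) for exon and intron lengths in bp.
#' @param n_exon_range Inclusive range of exons per gene.
#' @param keep_prob Probability that a non-full isoform keeps each exon.
#' @param chrom Virtual chromosome name.
#' @param gap_bp Gap between consecutive genes in bp.
#' @param seed Integer seed.
#' @return A [annotation()] object.
#' @export
simulate_annotation <- function(n_genes,
                                isoform_count_sampler = function(n) 1L + rpois(n, 6),
                                exon_length_menu = c(200L, 500L, 1000L, 2000L),
                                intron_length_menu = c(500L, 1000L, 2000L),
                                n_exon_range = c(2L, 10L),
                                keep_prob = 0.75,
                                chrom = "chrS",
                                gap_bp = 10000L,
                                seed = 42L) {
  stopifnot(n_genes >= 1)
  withr::with_seed(seed, {
    offset <- 0L
    rows <- vector("list", n_genes)
    n_iso <- pmax(1L, as.integer(isoform_count_sampler(n_genes)))
    for (i in seq_len(n_genes)) {
      k <- sample(seq(n_exon_range[1], n_exon_range[2]), 1)
      exon_lengths <- sample(exon_length_menu, k, replace = TRUE)
      intron_lengths <- if (k > 1) sample(intron_length_menu, k - 1, replace = TRUE) else integer(0)
      isoforms <- list(seq_len(k))
      if (n_iso[i] > 1) {
        for (j in seq_len(n_iso[i] - 1L)) {
          keep <- which(runif(k) < keep_prob)
          if (length(keep) == 0) keep <- sample(k, 1)
          isoforms <- c(isoforms, list(keep))
        }
      }
      # drop duplicated isoform structures
      isoforms <- isoforms[!duplicated(purrr::map_chr(isoforms, paste, collapse = ","))]
      gid <- sprintf("g%04d", i)
      names(isoforms) <- sprintf("%s.t%d", gid, seq_along(isoforms))
      rows[[i]] <- .gene_from_structure(
        gid, exon_lengths, intron_lengths, isoforms,
        strand = sample(c("+", "-"), 1), chrom = chrom, offset = offset
      )
      offset <- max(rows[[i]]$end) + gap_bp
    }
    annotation(bind_rows(rows))
  })
}

#' Build an expression profile
#'
#' An expression profile holds, per sample, the true molar fraction of each
#' transcript (`theta`, summing to 1 within a sample) and the target number of
#' sequenced fragments (`library_size`).
#'
#' @param theta A data frame with columns `sample`, `transcript_id`, `theta`.
#' @param library_size A single number, or a named vector/`tibble(sample,
#'   library_size)` giving per-sample fragment counts.
#' @return A tibble with columns `sample`, `transcript_id`, `theta`,
#'   `library_size`; `theta` renormalized checks apply (must already sum to 1
#'   per sample within 1e-6).
#' @export
expression_profile <- function(theta, library_size) {
  theta <- as_tibble(theta)
  stopifnot(all(c("sample", "transcript_id", "theta") %in% names(theta)))
  if (any(theta$theta < 0)) abort("theta must be non-negative")
  sums <- theta |>
    group_by(.data$sample) |>
    summarise(s = sum(.data$theta), .groups = "drop")
  if (any(abs(sums$s - 1) > 1e-6)) {
    abort("theta must sum to 1 within each sample")
  }
  if (is.data.frame(library_size)) {
    theta <- theta |> left_join(as_tibble(library_size), by = "sample")
  } else if (!is.null(names(library_size))) {
    theta$library_size <- unname(library_size[theta$sample])
  } else {
    stopifnot(length(library_size) == 1)
    theta$library_size <- library_size
  }
  if (any(theta$library_size < 1)) abort("library_size must be >= 1")
  theta
}

# transcript-coordinate exon map: per exon, its genomic span and its span in
# transcript coordinates (left-to-right genomically; orientation does not
# matter for block projection or uniform sampling)
.tx_exon_map <- function(ann) {
  ann$exons |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(
      exon_len = .data$end - .data$start,
      tx_end = cumsum(.data$exon_len),
      tx_start = .data$tx_end - .data$exon_len
    ) |>
    ungroup()
}

# project transcript-coordinate intervals [s, e) onto genomic blocks
.project_blocks <- function(intervals, exon_map) {
  intervals |>
    inner_join(exon_map, by = "transcript_id", relationship = "many-to-many") |>
    filter(.data$tx_s < .data$tx_end, .data$tx_e > .data$tx_start) |>
    mutate(
      block_start = .data$start + pmax(0L, .data$tx_s - .data$tx_start),
      block_end = .data$start + pmin(.data$exon_len, .data$tx_e - .data$tx_start)
    ) |>
    select("read_id", "chrom", start = "block_start", end = "block_end")
}

#' Simulate stranded spliced reads with ground truth
#'
#' Draws `library_size` fragments per sample. The transcript of origin is
#' sampled proportional to `theta` times the transcript's effective length
#' (number of valid start positions), so that read *shares* reflect both
#' molar abundance and length, as in a real uniform-fragmentation library.
#' The fragment start is uniform along the transcript and the genomic blocks
#' are obtained by projecting through the exon chain, so junction-spanning
#' reads arise naturally. With probability `intron_retention_rate` a read is
#' instead drawn uniformly from the gene's unspliced pre-mRNA span and
#' labelled `INTRON_RETENTION`.
#'
#' Transcripts shorter than the read (or fragment) length are excluded from
#' sampling with a warning; their probability mass is redistributed.
#'
#' @param ann A `tx_annotation`.
#' @param profile An [expression_profile()] (columns `sample`,
#'   `transcript_id`, `theta`, `library_size`).
#' @param cfg A [sim_config()].
#' @return A tibble of aligned blocks, one row per block, with columns
#'   `read_id`, `sample`, `chrom`, `strand`, `start`, `end`, `truth` (the
#'   originating `transcript_id`, or `"INTRON_RETENTION"`). A multi-block
#'   (junction-spanning) read contributes several rows sharing a `read_id`.
#' @export
simulate_reads <- function(ann, profile, cfg = sim_config()) {
  stopifnot(inherits(ann, "tx_annotation"), inherits(cfg, "sim_config"))
  profile <- as_tibble(profile)
  unknown <- setdiff(unique(profile$transcript_id), ann$transcripts$transcript_id)
  if (length(unknown) > 0) {
    abort(paste0("profile transcripts not in annotation: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  exon_map <- .tx_exon_map(ann)
  tx_info <- ann$transcripts
  gene_span <- ann$union_exons |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(g_start = min(.data$start), g_end = max(.data$end), .groups = "drop")

  withr::with_seed(cfg$seed, {
    out <- purrr::map(split(profile, profile$sample), function(pf) {
      smp <- pf$sample[1]
      n <- as.integer(pf$library_size[1])
      span_len <- if (cfg$paired) NULL else cfg$read_length_bp

      pf <- pf |> left_join(tx_info, by = "transcript_id")
      min_span <- if (cfg$paired) cfg$read_length_bp else cfg$read_length_bp
      short <- pf$theta > 0 & pf$length_bp < min_span
      if (any(short)) {
        warn(paste0("sample ", smp, ": ", sum(short),
                    " expressed transcript(s) shorter than the read length; skipped"))
        pf$theta[short] <- 0
      }
      if (sum(pf$theta) <= 0) abort("no expressible transcript in profile")
      eff <- pmax(1, pf$length_bp - cfg$read_length_bp + 1)
      w <- pf$theta * eff
      w <- w / sum(w)

      is_ir <- runif(n) < cfg$intron_retention_rate
      tx_idx <- sample.int(nrow(pf), n, replace = TRUE, prob = w)
      read_id <- sprintf("%s_r%07d", smp, seq_len(n))

      reads <- tibble(
        read_id = read_id,
        transcript_id = pf$transcript_id[tx_idx],
        gene_id = pf$gene_id[tx_idx],
        tx_len = pf$length_bp[tx_idx],
        tx_strand = pf$strand[tx_idx],
        is_ir = is_ir
      )

      # fragment span in transcript coordinates
      if (cfg$paired) {
        fl <- round(rnorm(n, cfg$fragment_length_mean, cfg$fragment_length_sd))
        fl <- pmin(pmax(fl, cfg$read_length_bp), reads$tx_len)
        reads$span <- as.integer(fl)
      } else {
        reads$span <- cfg$read_length_bp
      }
      reads$tx_s <- as.integer(floor(runif(n) * (reads$tx_len - reads$span + 1)))
      reads$tx_e <- reads$tx_s + reads$span

      read_strand <- switch(cfg$strand_protocol,
        reverse = .flip_strand(reads$tx_strand),
        forward = reads$tx_strand,
        unstranded = sample(c("+", "-"), n, replace = TRUE)
      )

      # mature-transcript reads: project through the exon chain
      mat <- reads |> filter(!.data$is_ir)
      if (cfg$paired) {
        # blocks are the union of both mates; a long inner gap leaves two
        # transcript-coordinate intervals
        gap_s <- mat$tx_s + cfg$read_length_bp
        gap_e <- mat$tx_e - cfg$read_length_bp
        has_gap <- gap_e > gap_s
        iv <- bind_rows(
          tibble(read_id = mat$read_id, transcript_id = mat$transcript_id,
                 tx_s = mat$tx_s,
                 tx_e = ifelse(has_gap, gap_s, mat$tx_e)),
          tibble(read_id = mat$read_id[has_gap],
                 transcript_id = mat$transcript_id[has_gap],
                 tx_s = gap_e[has_gap], tx_e = mat$tx_e[has_gap])
        )
      } else {
        iv <- mat |> select("read_id", "transcript_id", "tx_s", "tx_e")
      }
      mat_blocks <- .project_blocks(iv, exon_map)

      # intron-retention reads: uniform over the unspliced gene span
      irr <- reads |> filter(.data$is_ir)
      ir_blocks <- NULL
      if (nrow(irr) > 0) {
        irr <- irr |> left_join(gene_span, by = "gene_id")
        avail <- pmax(1L, (irr$g_end - irr$g_start) - irr$span + 1L)
        s <- irr$g_start + as.integer(floor(runif(nrow(irr)) * avail))
        ir_blocks <- tibble(
          read_id = irr$read_id, chrom = irr$chrom,
          start = s, end = pmin(s + irr$span, irr$g_end)
        )
      }

      meta <- tibble(
        read_id = reads$read_id,
        sample = smp,
        strand = read_strand,
        truth = ifelse(reads$is_ir, "INTRON_RETENTION", reads$transcript_id)
      )
      bind_rows(mat_blocks, ir_blocks) |>
        inner_join(meta, by = "read_id") |>
        select("read_id", "sample", "chrom", "strand", "start", "end", "truth") |>
        arrange(.data$read_id, .data$start)
    })
    bind_rows(out)
  })
}

#' Extract the per-read truth table from simulated reads
#'
#' @param reads A block tibble from [simulate_reads()].
#' @return One row per read: `read_id`, `sample`, `truth`.
#' @export
read_truth <- function(reads) {
  reads |> distinct(.data$read_id, .data$sample, .data$truth)
}

#' Write simulated reads as BED12
#'
#' One BED12 record per read; spliced alignment blocks are encoded in
#' `blockCount`/`blockSizes`/`blockStarts`, the name field is the read id and
#' the strand column is the read strand.
#'
#' @param reads A block tibble from [simulate_reads()] (one sample or many;
#'   all records are written in read order).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_bed12 <- function(reads, path) {
  per_read <- reads |>
    group_by(.data$read_id, .data$sample, .data$chrom, .data$strand) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(
      chromStart = min(.data$start),
      chromEnd = max(.data$end),
      blockCount = dplyr::n(),
      blockSizes = paste0(paste(.data$end - .data$start, collapse = ","), ","),
      blockStarts = paste0(paste(.data$start - min(.data$start), collapse = ","), ","),
      .groups = "drop"
    )
  readr::write_lines(
    paste(per_read$chrom, per_read$chromStart, per_read$chromEnd,
          per_read$read_id, 0L, per_read$strand,
          per_read$chromStart, per_read$chromEnd, "0,0,0",
          per_read$blockCount, per_read$blockSizes, per_read$blockStarts,
          sep = "\t"),
    path
  )
  invisible(path)
}

#' Read aligned spliced reads from BED12
#'
#' Parses a BED12 file (blocks = aligned segments, name = read id) into the
#' block tibble used by the counting and quantification steps.
#'
#' @param path Path to a BED12 file.
#' @param sample Sample label attached to all reads (default the file name).
#' @return A block tibble with columns `read_id`, `sample`, `chrom`,
#'   `strand`, `start`, `end`.
#' @export
read_reads_bed12 <- function(path, sample = basename(path)) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- as.data.frame(gr)
  bl <- as.data.frame(gr$blocks)  # one row per block, grouped by record
  rec <- bl$group
  tibble(
    read_id = df$name[rec],
    sample = sample,
    chrom = as.character(df$seqnames)[rec],
    strand = as.character(df$strand)[rec],
    # block starts are relative to the (1-based) record start
    start = (df$start[rec] - 1L) + (bl$start - 1L),
    end = (df$start[rec] - 1L) + bl$end
  )
}

#' Scenario presets for the quantification comparison
#'
#' Fully specified, seeded scenarios that reproduce in miniature the
#' situations driving the union-exon versus transcript-based comparison:
#'
#' \describe{
#'   \item{fig1}{one gene, isoform 1 with exons of 2/1/2 kb and isoform 2
#'     skipping the middle exon; union exons are 2, 1 and 2 kb.}
#'   \item{fig9}{one gene with exons of 2/2/1 kb; the short isoform `a` skips
#'     exon 2, the long isoform `b` keeps it. Two conditions: only `a`
#'     expressed, only `b` expressed.}
#'   \item{short_dominant}{a 3-isoform gene whose shortest isoform (500 bp
#'     against a 4.5 kb union model) carries 85\% of the molar abundance --
#'     the situation in which union-exon RPKM underestimates most severely.}
#'   \item{isoform_switch}{a two-isoform gene of equal-length isoforms that
#'     switches from (1, 0) in condition A to (0.25, 0.75) in condition B with
#'     unchanged gene totals, on top of 20 stably expressed background genes;
#'     2 + 2 replicate design.}
#'   \item{mixed}{`n_genes` random multi-isoform genes with log-normal gene
#'     abundances and Dirichlet-like isoform usage, identical in both
#'     conditions, 2 + 2 replicates, 4\% intron-retention reads.}
#' }
#'
#' @param name One of `"fig1"`, `"fig9"`, `"short_dominant"`,
#'   `"isoform_switch"`, `"mixed"`.
#' @param seed Integer seed used for the annotation (where random), the
#'   profile, and the returned [sim_config()].
#' @param library_size Fragments per sample.
#' @param n_genes Number of genes for `"mixed"`.
#' @return A list with elements `annotation`, `profile` (an
#'   [expression_profile()] covering all samples), `config` (a
#'   [sim_config()]), and `design` (tibble `sample`, `condition`).
#' @export
scenario_preset <- function(name = c("fig1", "fig9", "short_dominant",
                                     "isoform_switch", "mixed"),
                            seed = 42L,
                            library_size = 10000L,
                            n_genes = 200L) {
  name <- match.arg(name)
  cfg <- sim_config(seed = seed)
  if (name == "fig1") {
    ann <- annotation(.gene_from_structure(
      "G1", exon_lengths = c(2000L, 1000L, 2000L),
      intron_lengths = c(1000L, 1000L),
      isoforms = list(G1.t1 = c(1L, 2L, 3L), G1.t2 = c(1L, 3L))
    ))
    profile <- expression_profile(
      tibble(sample = "S1", transcript_id = c("G1.t1", "G1.t2"),
             theta = c(0.25, 0.75)),
      library_size
    )
    design <- tibble(sample = "S1", condition = "A")
  } else if (name == "fig9") {
    ann <- annotation(.gene_from_structure(
      "G1", exon_lengths = c(2000L, 2000L, 1000L),
      intron_lengths = c(1000L, 1000L),
      isoforms = list(G1.a = c(1L, 3L), G1.b = c(1L, 2L, 3L))
    ))
    profile <- expression_profile(
      bind_rows(
        tibble(sample = "A1", transcript_id = c("G1.a", "G1.b"), theta = c(1, 0)),
        tibble(sample = "B1", transcript_id = c("G1.a", "G1.b"), theta = c(0, 1))
      ),
      library_size
    )
    design <- tibble(sample = c("A1", "B1"), condition = c("A", "B"))
  } else if (name == "short_dominant") {
    ann <- annotation(.gene_from_structure(
      "G1", exon_lengths = c(250L, 250L, 1500L, 2500L),
      intron_lengths = c(800L, 800L, 800L),
      isoforms = list(
        G1.t1 = c(1L, 2L),          #  500 bp, dominant
        G1.t2 = c(1L, 3L),          # 1750 bp
        G1.t3 = c(1L, 2L, 3L, 4L)   # 4500 bp, full union model
      )
    ))
    profile <- expression_profile(
      tibble(sample = "S1",
             transcript_id = c("G1.t1", "G1.t2", "G1.t3"),
             theta = c(0.85, 0.10, 0.05)),
      library_size
    )
    design <- tibble(sample = "S1", condition = "A")
  } else if (name == "isoform_switch") {
    sw <- .gene_from_structure(
      "SW", exon_lengths = c(1000L, 500L, 500L, 1000L),
      intron_lengths = c(700L, 700L, 700L),
      isoforms = list(SW.a = c(1L, 2L, 4L), SW.b = c(1L, 3L, 4L)),
      chrom = "chrW"
    )
    bg <- simulate_annotation(20L, seed = seed,
                              isoform_count_sampler = function(n) 1L + rpois(n, 1))
    ann <- annotation(bind_rows(bg$exons, sw))
    samples <- c("A1", "A2", "B1", "B2")
    conditions <- c("A", "A", "B", "B")
    bg_theta <- withr::with_seed(seed + 1L, {
      g_w <- stats::setNames(stats::rlnorm(nrow(bg$genes), 0, 1), bg$genes$gene_id)
      tx_w <- stats::setNames(stats::rgamma(nrow(bg$transcripts), 1, 1) + 0.05,
                              bg$transcripts$transcript_id)
      bg$transcripts |>
        mutate(w = unname(tx_w[.data$transcript_id])) |>
        group_by(.data$gene_id) |>
        mutate(w = .data$w / sum(.data$w)) |>
        ungroup() |>
        mutate(w = .data$w * unname(g_w[.data$gene_id])) |>
        select("transcript_id", "w")
    })
    theta <- purrr::map2_dfr(samples, conditions, function(smp, cond) {
      sw_theta <- if (cond == "A") c(1, 0) else c(0.25, 0.75)
      tb <- bind_rows(
        bg_theta |> rename(theta = "w"),
        tibble(transcript_id = c("SW.a", "SW.b"),
               # the switch gene carries ~10% of the library
               theta = sw_theta * 0.1 * sum(bg_theta$w) / 0.9)
      )
      tb$theta <- tb$theta / sum(tb$theta)
      tb$sample <- smp
      tb
    })
    profile <- expression_profile(theta, library_size)
    design <- tibble(sample = samples, condition = conditions)
  } else { # mixed
    ann <- simulate_annotation(n_genes, seed = seed)
    samples <- c("A1", "A2", "B1", "B2")
    conditions <- c("A", "A", "B", "B")
    base_theta <- withr::with_seed(seed + 1L, {
      g_w <- stats::setNames(stats::rlnorm(nrow(ann$genes), 0, 1.5), ann$genes$gene_id)
      tx_w <- stats::rgamma(nrow(ann$transcripts), 1, 1) + 0.02
      ann$transcripts |>
        mutate(w = tx_w) |>
        group_by(.data$gene_id) |>
        mutate(w = .data$w / sum(.data$w)) |>
        ungroup() |>
        mutate(theta = .data$w * unname(g_w[.data$gene_id])) |>
        mutate(theta = .data$theta / sum(.data$theta)) |>
        select("transcript_id", "theta")
    })
    theta <- purrr::map_dfr(samples, ~ mutate(base_theta, sample = .x))
    profile <- expression_profile(theta, library_size)
    design <- tibble(sample = samples, condition = conditions)
    cfg <- sim_config(seed = seed, intron_retention_rate = 0.04)
  }
  list(annotation = ann, profile = profile, config = cfg, design = design)
}
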