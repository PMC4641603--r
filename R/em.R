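#' Build the read-transcript compatibility matrix
#'
#' The transcript-based counting rule: a read is compatible with an isoform
#' if and only if it overlaps it completely -- every aligned block lies inside
#' the isoform's exons and every inter-block gap coincides exactly with one of
#' the isoform's introns (and the strand matches the library protocol). A
#' junction-spanning read is therefore compatible only with isoforms carrying
#' that exact junction, and an intron-retention read, having bases inside an
#' intron of every isoform, is compatible with none and is dropped.
#'
#' Two containment conditions are checked per (read, transcript) pair: the
#' read's blocks must cover `read bases` of transcript exon (no block base in
#' an intron), and the transcript's exons restricted to the read's genomic
#' span must also cover exactly `read bases` (no transcript exon base inside a
#' read gap). Together these are equivalent to the block/intron statement
#' above.
#'
#' Reads sharing a compatibility set are collapsed into equivalence classes,
#' the standard sufficient statistic for the EM step.
#'
#' @param reads A block tibble (columns `read_id`, `sample`, `chrom`,
#'   `strand`, `start`, `end`).
#' @param ann A `tx_annotation`.
#' @param strand_mode `"reverse"` (default), `"forward"`, or `"unstranded"`.
#' @param eff_length `"corrected"` (default): effective length
#'   `max(1, length - read_length + 1)`, the number of valid start positions;
#'   `"plain"`: the transcript length itself.
#' @param read_length Read (or fragment) length used for the correction;
#'   when `NULL` it is inferred as the median number of aligned bases per
#'   read.
#' @return A list of class `compat_matrix`:
#'   \describe{
#'     \item{classes}{tibble `sample`, `class_id`, `n_reads`;}
#'     \item{members}{tibble `class_id`, `transcript_id` (class membership is
#'       sample-independent: the id encodes the transcript set);}
#'     \item{eff_lengths}{tibble `transcript_id`, `gene_id`, `length_bp`,
#'       `eff_length`;}
#'     \item{reads}{tibble `read_id`, `sample`, `class_id` for every
#'       compatible (non-dropped) read;}
#'     \item{summary}{tibble per sample with `n_reads`, `n_compatible`,
#'       `n_dropped`.}
#'   }
#' @export
build_compatibility <- function(reads, ann,
                                strand_mode = c("reverse", "forward", "unstranded"),
                                eff_length = c("corrected", "plain"),
                                read_length = NULL) {
  strand_mode <- match.arg(strand_mode)
  eff_length <- match.arg(eff_length)
  stopifnot(inherits(ann, "tx_annotation"))
  reads <- as_tibble(reads)

  read_info <- reads |>
    group_by(.data$read_id, .data$sample, .data$chrom, .data$strand) |>
    summarise(
      bases = sum(.data$end - .data$start),
      span_start = min(.data$start),
      span_end = max(.data$end),
      .groups = "drop"
    )
  if (is.null(read_length)) {
    read_length <- if (nrow(read_info) > 0) {
      as.integer(round(median(read_info$bases)))
    } else 1L
  }
  eff_lengths <- ann$transcripts |>
    mutate(eff_length = if (eff_length == "corrected") {
      pmax(1, .data$length_bp - .env$read_length + 1)
    } else {
      as.numeric(.data$length_bp)
    }) |>
    select("transcript_id", "gene_id", "length_bp", "eff_length")

  ex <- ann$exons
  # condition A: aligned bases of the read inside the transcript's exons
  b_ir <- IRanges::IRanges(reads$start + 1L, reads$end)
  e_ir <- IRanges::IRanges(ex$start + 1L, ex$end)
  hits <- IRanges::findOverlaps(b_ir, e_ir)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  keep <- reads$chrom[qi] == ex$chrom[si] &
    .strand_compatible(reads$strand[qi], ex$strand[si], strand_mode)
  qi <- qi[keep]; si <- si[keep]
  in_exon <- tibble(
    read_id = reads$read_id[qi],
    transcript_id = ex$transcript_id[si],
    ov = pmin(reads$end[qi], ex$end[si]) - pmax(reads$start[qi], ex$start[si])
  ) |>
    group_by(.data$read_id, .data$transcript_id) |>
    summarise(ov = sum(.data$ov), .groups = "drop")

  # condition B: transcript exon bases inside the read's genomic span
  s_ir <- IRanges::IRanges(read_info$span_start + 1L, read_info$span_end)
  hits2 <- IRanges::findOverlaps(s_ir, e_ir)
  q2 <- S4Vectors::queryHits(hits2)
  s2 <- S4Vectors::subjectHits(hits2)
  keep2 <- read_info$chrom[q2] == ex$chrom[s2]
  q2 <- q2[keep2]; s2 <- s2[keep2]
  in_span <- tibble(
    read_id = read_info$read_id[q2],
    transcript_id = ex$transcript_id[s2],
    span_ov = pmin(read_info$span_end[q2], ex$end[s2]) -
      pmax(read_info$span_start[q2], ex$start[s2])
  ) |>
    group_by(.data$read_id, .data$transcript_id) |>
    summarise(span_ov = sum(.data$span_ov), .groups = "drop")

  compat <- in_exon |>
    inner_join(in_span, by = c("read_id", "transcript_id")) |>
    inner_join(read_info |> select("read_id", "sample", "bases"), by = "read_id") |>
    filter(.data$ov == .data$bases, .data$span_ov == .data$bases) |>
    select("read_id", "sample", "transcript_id")

  sets <- compat |>
    group_by(.data$read_id, .data$sample) |>
    summarise(class_id = paste(sort(.data$transcript_id), collapse = "|"),
              .groups = "drop")
  classes <- sets |> count(.data$sample, .data$class_id, name = "n_reads")
  members <- classes |>
    distinct(.data$class_id) |>
    mutate(transcript_id = stringr::str_split(.data$class_id, stringr::fixed("|"))) |>
    tidyr::unnest("transcript_id")

  summary <- read_info |>
    count(.data$sample, name = "n_reads") |>
    left_join(sets |> count(.data$sample, name = "n_compatible"), by = "sample") |>
    mutate(
      n_compatible = tidyr::replace_na(.data$n_compatible, 0L),
      n_dropped = .data$n_reads - .data$n_compatible
    )

  structure(
    list(classes = classes, members = members, eff_lengths = eff_lengths,
         reads = sets, summary = summary, read_length = read_length),
    class = "compat_matrix"
  )
}

#' @export
print.compat_matrix <- function(x, ...) {
  cat("<compat_matrix> ", nrow(x$members |> distinct(.data$class_id)),
      " equivalence classes over ", nrow(x$eff_lengths), " transcripts\n", sep = "")
  print(x$summary)
  invisible(x)
}

# EM for one sample given integer class counts and a members index
.em_one_sample <- function(class_counts, members, eff_lengths, tol, max_iter) {
  tx <- eff_lengths$transcript_id
  len <- eff_lengths$eff_length
  ji <- match(members$transcript_id, tx)
  ki <- match(members$class_id, class_counts$class_id)
  ok <- !is.na(ki)
  ji <- ji[ok]; ki <- ki[ok]
  n_k <- class_counts$n_reads
  n_total <- sum(n_k)
  m <- length(tx)

  theta <- rep(1 / m, m)
  loglik <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- theta[ji] / len[ji]
    denom <- rowsum(w, ki)[, 1]
    ll <- sum(n_k * log(denom))
    trace <- c(trace, ll)
    resp <- n_k[ki] * w / denom[ki]
    c_t <- rep(0, m)
    agg <- rowsum(resp, ji)
    c_t[as.integer(rownames(agg))] <- agg[, 1]
    theta_new <- c_t / n_total
    delta <- max(abs(theta_new - theta))
    theta <- theta_new
    loglik <- ll
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  # final expected counts under the converged abundances
  w <- theta[ji] / len[ji]
  denom <- rowsum(w, ki)[, 1]
  resp <- n_k[ki] * w / denom[ki]
  c_t <- rep(0, m)
  agg <- rowsum(resp, ji)
  c_t[as.integer(rownames(agg))] <- agg[, 1]

  list(theta = theta, expected_count = c_t, n_iterations = iter,
       converged = converged, loglik = sum(n_k * log(denom)),
       loglik_trace = trace, n_reads = n_total)
}

#' Estimate isoform abundances by expectation-maximization
#'
#' Starts from the assumption that all isoforms are equally expressed, splits
#' each equivalence class of reads among its compatible isoforms in
#' proportion to abundance per effective base, re-estimates the abundances
#' from the expected counts, and repeats until the largest abundance change
#' falls below `tol`. The expected read count of a transcript is the sum of
#' its final read responsibilities, so expected counts are generally
#' fractional and always sum to the number of compatible reads.
#'
#' The EM iterates on the fraction of reads attributable to each isoform
#' (`read_fraction`, the direct M-step quantity). The reported `theta` is the
#' molar relative abundance obtained by dividing read fractions by effective
#' length and renormalizing -- the fraction of transcript molecules, the
#' quantity the simulator's expression profiles specify. The two coincide
#' when all isoforms have equal effective length, and at the degenerate
#' single-isoform corners.
#'
#' @param cm A [build_compatibility()] result.
#' @param tol Convergence tolerance on `max |delta theta|` (default 1e-8).
#' @param max_iter Maximum EM iterations (default 1000); if reached, the
#'   result is returned with `converged = FALSE`.
#' @return A list of class `isoform_fit`:
#'   \describe{
#'     \item{estimates}{tibble `sample`, `transcript_id`, `gene_id`,
#'       `theta` (molar abundance), `read_fraction`, `expected_count`,
#'       `eff_length`, `length_bp`;}
#'     \item{stats}{tibble per sample: `n_reads_used`, `n_reads_dropped`,
#'       `n_iterations`, `converged`, `loglik`;}
#'     \item{loglik_trace}{named list of per-iteration log-likelihoods.}
#'   }
#' @export
em_quantify <- function(cm, tol = 1e-8, max_iter = 1000L) {
  stopifnot(inherits(cm, "compat_matrix"))
  samples <- cm$summary$sample
  ests <- list(); stats <- list(); traces <- list()
  for (smp in samples) {
    cls <- cm$classes |> filter(.data$sample == smp)
    dropped <- cm$summary$n_dropped[cm$summary$sample == smp]
    if (nrow(cls) == 0) {
      ests[[smp]] <- cm$eff_lengths |>
        mutate(sample = smp, theta = NA_real_, read_fraction = NA_real_,
               expected_count = 0)
      stats[[smp]] <- tibble(
        sample = smp, n_reads_used = 0L, n_reads_dropped = dropped,
        n_iterations = 0L, converged = TRUE, loglik = NA_real_
      )
      traces[[smp]] <- numeric(0)
      next
    }
    fit <- .em_one_sample(cls, cm$members, cm$eff_lengths, tol, max_iter)
    dens <- fit$theta / cm$eff_lengths$eff_length
    ests[[smp]] <- cm$eff_lengths |>
      mutate(sample = smp, theta = dens / sum(dens), read_fraction = fit$theta,
             expected_count = fit$expected_count)
    stats[[smp]] <- tibble(
      sample = smp, n_reads_used = fit$n_reads, n_reads_dropped = dropped,
      n_iterations = fit$n_iterations, converged = fit$converged,
      loglik = fit$loglik
    )
    traces[[smp]] <- fit$loglik_trace
  }
  structure(
    list(
      estimates = bind_rows(ests) |>
        select("sample", "transcript_id", "gene_id", "theta", "read_fraction",
               "expected_count", "eff_length", "length_bp"),
      stats = bind_rows(stats),
      loglik_trace = traces
    ),
    class = "isoform_fit"
  )
}

#' @export
print.isoform_fit <- function(x, ...) {
  cat("<isoform_fit> ", dplyr::n_distinct(x$estimates$transcript_id),
      " transcripts x ", nrow(x$stats), " sample(s)\n", sep = "")
  print(x$stats)
  invisible(x)
}

#' Tidiers for unionexon result objects
#'
#' `tidy()` returns the per-feature table of a result (counts or estimates);
#' `glance()` returns its one-row-per-sample summary.
#'
#' @param x A `union_counts`, `isoform_fit` or `de_result` object.
#' @param ... Unused.
#' @name tidy-unionexon
#' @rdname tidy-unionexon
#' @export
tidy.isoform_fit <- function(x, ...) x$estimates

#' @rdname tidy-unionexon
#' @export
glance.isoform_fit <- function(x, ...) x$stats

#' One-step transcript quantification
#'
#' Convenience wrapper: [build_compatibility()] followed by [em_quantify()].
#'
#' @inheritParams build_compatibility
#' @inheritParams em_quantify
#' @return An `isoform_fit`.
#' @export
quantify_isoforms <- function(reads, ann,
                              strand_mode = c("reverse", "forward", "unstranded"),
                              eff_length = c("corrected", "plain"),
                              read_length = NULL,
                              tol = 1e-8, max_iter = 1000L) {
  cm <- build_compatibility(reads, ann, strand_mode = match.arg(strand_mode),
                            eff_length = match.arg(eff_length),
                            read_length = read_length)
  em_quantify(cm, tol = tol, max_iter = max_iter)
}

#' Sum isoform expected counts to genes
#'
#' Gene-level counts under the transcript-based approach: the expected counts
#' of a gene's isoforms are added up.
#'
#' @param fit An `isoform_fit`.
#' @param ann A `tx_annotation`; defines the gene universe (genes without
#'   estimated transcripts get zero).
#' @return A tibble `gene_id`, `sample`, `rsem_count`.
#' @export
gene_counts_from_isoforms <- function(fit, ann) {
  stopifnot(inherits(fit, "isoform_fit"), inherits(ann, "tx_annotation"))
  samples <- unique(fit$estimates$sample)
  per_gene <- fit$estimates |>
    group_by(.data$gene_id, .data$sample) |>
    summarise(rsem_count = sum(.data$expected_count), .groups = "drop")
  tidyr::expand_grid(gene_id = ann$genes$gene_id, sample = samples) |>
    left_join(per_gene, by = c("gene_id", "sample")) |>
    mutate(rsem_count = tidyr::replace_na(.data$rsem_count, 0))
}
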