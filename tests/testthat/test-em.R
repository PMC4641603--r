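test_that("strict compatibility distinguishes shared, junction and intronic reads", {
  ann <- two_isoform_ann()  # t1 = exons 1+2+3, t2 = exons 1+3
  compat_of <- function(blocks) {
    cm <- build_compatibility(blocks, ann)
    if (nrow(cm$reads) == 0) return(character(0))
    sort(cm$members$transcript_id[cm$members$class_id == cm$reads$class_id])
  }
  blk <- function(starts, ends, id = "r") {
    tibble::tibble(read_id = id, sample = "s1", chrom = "chr1", strand = "-",
                   start = as.integer(starts), end = as.integer(ends))
  }

  # read inside the shared first exon: compatible with both isoforms
  expect_equal(compat_of(blk(100, 175)), c("G1.t1", "G1.t2"))
  # read inside exon 2 (only t1 has it)
  expect_equal(compat_of(blk(3100, 3175)), "G1.t1")
  # junction read exon1->exon3 skips exon 2: only t2 carries that junction
  expect_equal(compat_of(blk(c(1960, 5000), c(2000, 5035))), "G1.t2")
  # junction read exon1->exon2 belongs to t1 only
  expect_equal(compat_of(blk(c(1960, 3000), c(2000, 3035))), "G1.t1")
  # read with a block inside an intron of every isoform is dropped
  expect_equal(compat_of(blk(c(1950, 2400), c(2000, 2425))), character(0))
  expect_equal(compat_of(blk(2200, 2275)), character(0))
  # wrong-strand read is dropped under the reverse protocol
  cm <- build_compatibility(blk(100, 175) |> dplyr::mutate(strand = "+"), ann)
  expect_equal(nrow(cm$reads), 0)
})

test_that("EM handles the degenerate single- and symmetric two-isoform cases", {
  # single transcript, 100 reads
  cm1 <- manual_compat(list(1L), 100L, tx_ids = "T1", gene_ids = "G",
                       eff_len = 900)
  fit1 <- em_quantify(cm1)
  expect_equal(fit1$estimates$theta, 1)
  expect_equal(fit1$estimates$expected_count, 100)

  # two structurally identical isoforms sharing all 100 reads: split 50/50
  cm2 <- manual_compat(list(c(1L, 2L)), 100L, tx_ids = c("T1", "T2"),
                       gene_ids = c("G", "G"), eff_len = c(900, 900))
  fit2 <- em_quantify(cm2)
  expect_equal(fit2$estimates$expected_count, c(50, 50))
  expect_equal(fit2$estimates$theta, c(0.5, 0.5))
})

test_that("EM matches a grid-search likelihood maximizer on two-isoform data", {
  # interior optimum: unique evidence for both isoforms plus shared reads
  sets <- list(1L, 2L, c(1L, 2L))
  counts <- c(20L, 30L, 50L)
  eff <- c(1000, 2000)
  cm <- manual_compat(sets, counts, tx_ids = c("A", "B"),
                      gene_ids = c("G", "G"), eff_len = eff)
  fit <- em_quantify(cm, tol = 1e-12, max_iter = 10000)
  oracle <- grid_mle_2tx(sets, counts, eff)
  expect_lt(max(abs(fit$estimates$read_fraction - oracle)), 1e-3)

  # boundary optimum: 30 reads unique to the long isoform, 30 shared
  sets2 <- list(2L, c(1L, 2L))
  counts2 <- c(30L, 30L)
  cm2 <- manual_compat(sets2, counts2, tx_ids = c("A", "B"),
                       gene_ids = c("G", "G"), eff_len = eff)
  fit2 <- em_quantify(cm2, tol = 1e-14, max_iter = 300000)
  oracle2 <- grid_mle_2tx(sets2, counts2, eff)
  expect_lt(max(abs(fit2$estimates$read_fraction - oracle2)), 1e-3)
  # expected counts at the optimum agree too
  theta <- oracle2
  dens <- theta / eff
  c_oracle <- c(0, counts2[1]) + counts2[2] * dens / sum(dens)
  expect_lt(max(abs(fit2$estimates$expected_count - c_oracle)), 1e-3)
})

test_that("EM conserves reads and its log-likelihood never decreases", {
  fig1 <- scenario_preset("fig1", seed = 31, library_size = 4000)
  reads <- simulate_reads(fig1$annotation, fig1$profile, fig1$config)
  cm <- build_compatibility(reads, fig1$annotation)
  fit <- em_quantify(cm, tol = 1e-10)
  st <- glance(fit)
  expect_equal(sum(fit$estimates$expected_count), st$n_reads_used)
  expect_equal(sum(fit$estimates$theta), 1)
  trace <- fit$loglik_trace[[st$sample]]
  expect_true(all(diff(trace) > -1e-8))
})

test_that("gene counts are isoform sums; transcript-dropped reads shrink them", {
  cm <- manual_compat(list(1L, 2L), c(10L, 22L), tx_ids = c("T1", "T2"),
                      gene_ids = c("G", "G"), eff_len = c(500, 800))
  fit <- em_quantify(cm)
  ann <- annotation(tibble::tibble(
    gene_id = "G", transcript_id = c("T1", "T2"), chrom = "c", strand = "+",
    start = c(0L, 0L), end = c(500L, 800L)
  ))
  gc <- gene_counts_from_isoforms(fit, ann)
  expect_equal(gc$rsem_count, 32)

  # empty estimates give zeros over the gene universe
  cm0 <- build_compatibility(
    tibble::tibble(read_id = "r", sample = "s1", chrom = "c", strand = "-",
                   start = 1000L, end = 1075L),
    ann
  )
  fit0 <- em_quantify(cm0)
  expect_equal(gene_counts_from_isoforms(fit0, ann)$rsem_count, 0)

  # with intron retention, union counts dominate EM gene counts
  mx <- scenario_preset("mixed", seed = 41, library_size = 2000, n_genes = 10)
  reads <- simulate_reads(mx$annotation, mx$profile,
                          sim_config(seed = 41, intron_retention_rate = 0.08))
  fc <- tidy(count_union(reads, mx$annotation))
  rc <- gene_counts_from_isoforms(quantify_isoforms(reads, mx$annotation),
                                  mx$annotation)
  cmp <- dplyr::inner_join(fc, rc, by = c("gene_id", "sample"))
  expect_true(all(cmp$rsem_count <= cmp$count + 1e-8))
})

test_that("abundance recovery degrades gracefully at low depth", {
  fig9 <- scenario_preset("fig9")
  err_at <- function(n, seed) {
    prof <- expression_profile(
      tibble::tibble(sample = "s1", transcript_id = c("G1.a", "G1.b"),
                     theta = c(0.3, 0.7)), n)
    reads <- simulate_reads(fig9$annotation, prof, sim_config(seed = seed))
    fit <- quantify_isoforms(reads, fig9$annotation)
    mean(abs(fit$estimates$theta - c(0.3, 0.7)))
  }
  errs <- vapply(1:20, function(s) c(err_at(20, s), err_at(300, s)),
                 numeric(2))
  expect_gt(mean(errs[1, ]), mean(errs[2, ]))
})
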