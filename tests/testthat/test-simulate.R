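test_that("presets encode the intended gene structures", {
  fig1 <- scenario_preset("fig1")
  ue <- fig1$annotation$union_exons
  expect_equal(ue$end - ue$start, c(2000L, 1000L, 2000L))
  expect_equal(fig1$annotation$transcripts$length_bp[
    fig1$annotation$transcripts$transcript_id == "G1.t2"], 4000L)

  fig9 <- scenario_preset("fig9")
  tx <- fig9$annotation$transcripts
  expect_equal(tx$length_bp[tx$transcript_id == "G1.a"], 3000L)
  expect_equal(tx$length_bp[tx$transcript_id == "G1.b"], 5000L)
  # isoform a skips exon 2
  ex_a <- fig9$annotation$exons |> dplyr::filter(transcript_id == "G1.a")
  expect_equal(nrow(ex_a), 2)

  sd <- scenario_preset("short_dominant")
  th <- sd$profile |> dplyr::arrange(dplyr::desc(theta))
  lens <- sd$annotation$transcripts$length_bp
  expect_gte(max(th$theta), 0.8)
  expect_gte(max(lens) / min(lens), 5)

  sw <- scenario_preset("isoform_switch", library_size = 100)
  th_sw <- sw$profile |>
    dplyr::filter(transcript_id %in% c("SW.a", "SW.b")) |>
    dplyr::left_join(sw$design, by = "sample")
  ratios <- th_sw |>
    dplyr::group_by(sample, condition) |>
    dplyr::summarise(frac = theta[transcript_id == "SW.a"] / sum(theta),
                     .groups = "drop")
  expect_true(all(ratios$frac[ratios$condition == "A"] == 1))
  expect_true(all(abs(ratios$frac[ratios$condition == "B"] - 0.25) < 1e-12))
})

test_that("simulated read count, placement and strand obey the model", {
  ann <- annotation(tibble::tibble(
    gene_id = "S", transcript_id = "S.t1", chrom = "c", strand = "+",
    start = 0L, end = 1000L
  ))
  prof <- expression_profile(
    tibble::tibble(sample = "s1", transcript_id = "S.t1", theta = 1), 100
  )
  reads <- simulate_reads(ann, prof, sim_config(seed = 7))
  expect_equal(dplyr::n_distinct(reads$read_id), 100)  # conservation
  expect_true(all(reads$start >= 0 & reads$end <= 1000))
  expect_true(all(reads$end - reads$start == 75))
  expect_true(all(read_truth(reads)$truth == "S.t1"))
  # reverse protocol: read strand opposite the gene strand
  expect_true(all(reads$strand == "-"))

  fwd <- simulate_reads(ann, prof, sim_config(seed = 7, strand_protocol = "forward"))
  expect_true(all(fwd$strand == "+"))
})

test_that("reads from an exon-skipping isoform avoid the skipped exon", {
  fig9 <- scenario_preset("fig9", seed = 5, library_size = 3000)
  reads <- simulate_reads(fig9$annotation, fig9$profile, fig9$config)
  a_reads <- reads |> dplyr::filter(sample == "A1")  # only G1.a expressed
  # exon 2 occupies (3000, 5000); no block of an A1 read may touch it
  expect_true(all(a_reads$end <= 3000 | a_reads$start >= 5000))
  # junction reads across exon1-exon3 exist: two blocks, gap over exons 2
  n_blocks <- a_reads |> dplyr::count(read_id)
  expect_gt(sum(n_blocks$n == 2), 0)
})

test_that("every mature read is compatible with its transcript of origin", {
  mx <- scenario_preset("mixed", seed = 9, library_size = 1500, n_genes = 15)
  reads <- simulate_reads(mx$annotation, mx$profile, mx$config)
  cm <- build_compatibility(reads, mx$annotation)
  truth <- read_truth(reads) |> dplyr::filter(truth != "INTRON_RETENTION")
  checked <- truth |>
    dplyr::inner_join(cm$reads, by = c("read_id", "sample")) |>
    dplyr::left_join(cm$members, by = "class_id",
                     relationship = "many-to-many") |>
    dplyr::group_by(read_id, sample) |>
    dplyr::summarise(ok = any(transcript_id == truth), .groups = "drop")
  # no mature read is dropped, and each one's class contains its true isoform
  expect_equal(nrow(checked), nrow(truth))
  expect_true(all(checked$ok))
})

test_that("intron-retention fraction matches the binomial model", {
  ann <- scenario_preset("fig9")$annotation
  prof <- expression_profile(
    tibble::tibble(sample = "s1", transcript_id = c("G1.a", "G1.b"),
                   theta = c(0.5, 0.5)),
    10000
  )
  reads <- simulate_reads(ann, prof, sim_config(seed = 21, intron_retention_rate = 0.1))
  frac <- mean(read_truth(reads)$truth == "INTRON_RETENTION")
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 10000))
})

test_that("simulation is deterministic under a fixed seed", {
  mx <- scenario_preset("mixed", seed = 1, library_size = 800, n_genes = 20)
  r1 <- simulate_reads(mx$annotation, mx$profile, mx$config)
  mx2 <- scenario_preset("mixed", seed = 1, library_size = 800, n_genes = 20)
  r2 <- simulate_reads(mx2$annotation, mx2$profile, mx2$config)
  expect_identical(r1, r2)
  r3 <- simulate_reads(mx$annotation, mx$profile, sim_config(seed = 2, intron_retention_rate = 0.04))
  expect_false(identical(r1, r3))
})

test_that("per-transcript read shares follow theta weighted by effective length", {
  fig9 <- scenario_preset("fig9")
  prof <- expression_profile(
    tibble::tibble(sample = "s1", transcript_id = c("G1.a", "G1.b"),
                   theta = c(0.3, 0.7)),
    20000
  )
  reads <- simulate_reads(fig9$annotation, prof, sim_config(seed = 13))
  eff <- c(3000, 5000) - 75 + 1
  p_a <- 0.3 * eff[1] / (0.3 * eff[1] + 0.7 * eff[2])
  share_a <- mean(read_truth(reads)$truth == "G1.a")
  expect_lt(abs(share_a - p_a), 3 * sqrt(p_a * (1 - p_a) / 20000))
})

test_that("too-short transcripts are skipped with a warning", {
  ann <- annotation(tibble::tibble(
    gene_id = c("A", "B"), transcript_id = c("A.t", "B.t"),
    chrom = "c", strand = "+",
    start = c(0L, 5000L), end = c(40L, 6000L)
  ))
  prof <- expression_profile(
    tibble::tibble(sample = "s1", transcript_id = c("A.t", "B.t"),
                   theta = c(0.5, 0.5)),
    50
  )
  expect_warning(reads <- simulate_reads(ann, prof, sim_config(seed = 2)),
                 "shorter than the read length")
  expect_true(all(read_truth(reads)$truth == "B.t"))
  expect_equal(dplyr::n_distinct(reads$read_id), 50)
})

test_that("BED12 output round-trips spliced blocks", {
  fig9 <- scenario_preset("fig9", seed = 3, library_size = 200)
  reads <- simulate_reads(fig9$annotation, fig9$profile, fig9$config) |>
    dplyr::filter(sample == "A1")
  path <- withr::local_tempfile(fileext = ".bed")
  write_reads_bed12(reads, path)
  back <- read_reads_bed12(path, sample = "A1")
  orig <- reads |> dplyr::select(read_id, chrom, strand, start, end) |>
    dplyr::arrange(read_id, start)
  rt <- back |> dplyr::select(read_id, chrom, strand, start, end) |>
    dplyr::arrange(read_id, start)
  expect_equal(as.data.frame(rt), as.data.frame(orig))
})
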