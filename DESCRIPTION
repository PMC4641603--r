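Package: unionexon
Title: Union-Exon Versus Transcript-Based RNA-Seq Gene Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A side-by-side comparison pipeline for the two dominant styles of
    RNA-seq gene quantification: 'union exon' counting, in which all overlapping
    exons of a gene are flattened into disjoint union exons and reads are counted
    against them with a partial-overlap rule, and transcript-based estimation, in
    which reads are assigned to isoforms by an expectation-maximization algorithm
    and gene expression is obtained by summing isoform abundances. The package
    parses GTF annotation into a tidy gene/transcript/exon model, simulates
    stranded spliced reads (including intron-retention reads and isoform-switch
    designs) with ground truth, implements both counting semantics, computes the
    three gene RPKM variants plus TPM, and provides the downstream analyses that
    contrast the approaches: per-gene expression ratios, cumulative distributions,
    structural binning, per-sample means with a paired underestimation test, and
    gene-level versus transcript-level differential-expression set comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
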