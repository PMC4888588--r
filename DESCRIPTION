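Package: karyoHMM
Title: Single-Cell Copy-Number Calling and Karyotype Heterogeneity
    Scoring with a Negative-Binomial Hidden Markov Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Copy-number analysis of low-coverage single-cell
    whole-genome-sequencing libraries. Reads are counted in
    mappability-derived variable-width genomic bins and corrected for GC
    bias; per-cell integer copy-number states (nullisomy up to decasomy)
    are inferred with a hidden Markov model whose emissions are tied
    negative binomial distributions plus a delta-distributed nullisomy
    state, fitted by the Baum-Welch algorithm and decoded by maximum
    posterior probability. Library quality is assessed by multivariate
    clustering of spikiness, model loglikelihood, segment counts and the
    Bhattacharyya distance between emission distributions. Population
    karyotypes are summarised by aneuploidy and heterogeneity scores,
    genome-wide and per chromosome, with pseudo-bulk aggregation,
    profile-similarity clustering and genome-wide heatmaps. A synthetic
    cohort simulator with clonal karyotypes, whole-chromosome
    mis-segregation and negative-binomial count noise supports testing
    of every stage without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    tools,
    cluster,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
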