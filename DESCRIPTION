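Package: foldscape
Title: Single-Molecule RNA Structure Landscapes from Chemical Probing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Reconstructs RNA conformational landscapes from single-molecule
    chemical-probing experiments read out on long-read sequencers. Aligned
    reads are converted into per-molecule mutation bit vectors, from which
    SHAPE reactivity profiles are computed. Each molecule is folded
    individually with a stochastic context-free grammar sampler under hard
    single-strandedness constraints derived from its own mutation pattern.
    Sampled structures are encoded as structural-element strings, embedded
    by PCA or MDS, and clustered into conformations with per-cluster
    proportions, representative structures, base-pair probabilities,
    single-strandedness likelihoods and positional Shannon entropies. A
    synthetic-probing simulator generates ground-truth conformational
    mixtures so the whole pipeline can be exercised without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    cluster,
    jsonlite,
    yaml,
    withr,
    Biostrings,
    Rsamtools,
    GenomicAlignments
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
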