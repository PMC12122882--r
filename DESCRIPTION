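Package: clonarch
Title: Clonal Architecture Simulation and Mutation Burden Estimation for
    Hypomutated Tumours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates tumour clonal architectures (comb-like polyclonal
    trees versus clonal-sweep trees) together with the sequencing
    observations used to study them: bulk whole-genome read counts,
    single-molecule duplex (NanoSeq-style) read bundles, and multi-biopsy
    genotype matrices. Implements duplex consensus calling and
    per-diploid-genome burden estimation, bulk substitution post-processing
    filters with depth downsampling, a phylogeny-construction filter stack
    with maximum-parsimony tree building and maximum-likelihood assignment
    of mutations to branches, tree-shape and burden-discrepancy statistics,
    and rule-based cancer driver annotation. The pipeline quantifies how a
    short-trunked, deeply branching clonal architecture causes bulk
    sequencing to under-report the true per-cell mutation burden.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
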