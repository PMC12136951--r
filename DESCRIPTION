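Package: lichenatlas
Title: Downstream Quantification for Lichen Holobiont Metagenome Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reusable building blocks for the downstream, post-assembly side
    of a lichen holobiont metagenome survey: assembly quality control (N50,
    large-contig counts, sample inclusion rules), consensus superkingdom
    assignment from two independent contig classifiers, coverage-weighted
    relative-abundance profiling, MAG quality tiering and two-proxy genus
    occurrence (MAGs vs 16S rRNA best hits), depth-normalised biosynthetic
    gene cluster (BGC) accounting, gene-cluster-family (GCF) construction
    with genus-specificity testing via rank-based ANOSIM on Bray-Curtis
    distances, and Tanimoto structural-similarity networking of lichen
    metabolites. Ships a synthetic holobiont generator that emulates the
    statistical structure such surveys assume, so the entire pipeline is
    testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
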