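Package: derepkit
Title: K-mer Based Dereplication of Prokaryotic Genome Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free dereplication of large prokaryotic genome
    collections. Genomes are compared through their sets of nucleotide k-mers
    using the exact Jaccard index, the Identical Genome Fraction (a
    containment-style similarity robust to partial genomes), or a
    bottom-sketch estimate of the Jaccard index. Candidate representatives
    are ordered by an equal-weight sum-of-ranks over configurable assembly,
    annotation and contamination quality metrics, then clustered greedily
    (loose or strict single-linkage) inside packs within an iterative
    divide-and-conquer engine with three stop criteria. Includes per-genome
    assembly statistics (N50/L50 family), annotation certainty and
    completeness, SSU rRNA chimera flagging, diversity and redundancy
    reporting of the representative set, and a synthetic genome-family
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    tibble,
    yaml,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
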