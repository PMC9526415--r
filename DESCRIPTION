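Package: alkscan
Title: Detection and Characterization of alkB-Anchored Alkane-Degradation Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects alkB-anchored alkane-degradation (alk) gene clusters in
    prokaryotic genome assemblies by marker co-localization, extracts and
    re-annotates the 38-kb alk-fragments around each qualifying alkB anchor,
    characterizes insertion-sequence (IS) elements, gene organization types,
    replicon location and GC signature of the clusters, and tests the
    monophyly of cluster-derived alkB genes on neighbor-joining trees.
    Includes a synthetic-genome generator with planted ground truth so the
    whole survey can be exercised and scored without any downloads.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
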