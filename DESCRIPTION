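Package: mimicqc
Title: Artifact Detection and Quantification for Transfected miRNA Mimic
    Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and classifies the artifact RNA species that arise when
    synthetic miRNA mimics are transfected into cells and profiled by small
    RNA sequencing: mutated (single-deletion) guide strands, unnatural
    antisense passenger strands, and high molecular weight species formed by
    concatemerization, 5'/3' non-templated tailing and polyadenylation.
    Provides a seeded FASTQ simulator with per-read truth labels, adapter
    trimming and length/contaminant/abundance filtering, an edit-distance
    classifier with concatemer decomposition, length histograms and windowed
    fold changes, plus the accompanying bench quantification conventions:
    delta-delta-Ct fold change, internal-control normalization, spike-in
    ladder copies-per-cell estimation, and division-normalized decay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    IRanges,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
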