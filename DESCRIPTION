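Package: anchorpair
Title: Linkage-Map Anchoring and Comparative Analysis of Haplotype-Resolved
    Genome Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A post-assembly comparative toolkit for a pair of
    haplotype-resolved genome assemblies, such as the two parental genomes
    assembled from a single F1 hybrid. Anchors contigs to linkage groups
    from genetic-map marker hits, orders and orients them, and emits AGP
    scaffolds; interprets whole-genome alignments (PAF) for one-to-one
    aligned fraction, large duplications, nonaligning regions, and
    inversions; computes repeat-interval statistics including
    contig-terminus enrichment; discovers tandem k-mer satellites with
    rotational canonicalization and screens them across samples; and
    matches gene models across annotations by reciprocal best hits,
    coordinate lift-over, and exon overlap. Includes a fully truth-tracked
    synthetic-data generator (diverged genome pair, simulated F2 crosses,
    derived evidence files) so that every stage can be validated without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
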