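Package: radmap
Title: ddRAD Linkage Mapping and Genome Anchoring for Outbred F1 Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for double-digest RADseq genotyping-by-sequencing in
    cross-pollinated F1 (pseudo-testcross) populations: an in-silico ddRAD
    simulator (genomes with repeat families, parental haplotypes, F1
    gametes, restriction digest and barcoded reads), read demultiplexing
    and quality filtering, seed-and-verify tag alignment against unmasked,
    repeat-masked or gene-model references, marker discovery with CP
    segregation coding, recombination-bin collapsing, two-point linkage
    map construction with Kosambi distances, reference-strategy
    concordance evaluation, genetic-map-guided scaffold anchoring with AGP
    output, and within-genome heterozygosity scanning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    data.table,
    igraph,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR
SystemRequirements: C++17
Config/testthat/edition: 3
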