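Package: allodonor
Title: Donor Genome Inference for Allotetraploids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify the maternal and paternal diploid donors of an
    allotetraploid genome. Implements chloroplast consensus building with a
    phred-quality variant filter, per-gene nucleotide diversity, neighbor-joining
    phylogenies with bootstrap and Robinson-Foulds tree comparison, collinear
    synteny-block chaining, Nei-Gojobori (1986) synonymous substitution (Ks)
    estimation with kernel-density modal-peak detection, depth-of-coverage
    contig classification from progenitor reads, gene-family copy-number
    amplification analysis, and k-mer based genome-size estimation. A seeded
    synthetic-allotetraploid generator provides truth-labelled data so the
    whole pipeline can be exercised and validated end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
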