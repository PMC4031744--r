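Package: denovok
Title: Reference-Free De Novo Mutation Discovery by Direct K-mer Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects de novo mutations by comparing the k-mer content of an
    affected sample directly against related unaffected samples (the two
    parents of a family trio, or matched normal tissue), without first
    aligning reads to a reference genome.  Proband k-mers surviving a
    sequencing-error count filter, vector and reference-exome screens, and
    subtraction of both unaffected samples are traced back to their reads,
    micro-assembled into short contigs, re-examined against parental read
    coverage to remove capture-dropout artifacts, and finally converted to
    annotated variant calls.  Includes a synthetic diploid trio/pair
    simulator with planted de novo variants, mosaic fractions, sequencing
    error, vector contamination and capture dropout, so the whole pipeline
    is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    BiocGenerics,
    jsonlite,
    withr
Config/testthat/edition: 3
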