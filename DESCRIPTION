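Package: teloseeker
Title: Telomerase RNA Discovery and Telomere Motif Prediction from
    Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for identifying candidate telomerase RNAs (TRs) in de
    novo assembled transcriptomes and predicting the telomere repeat they
    template. Implements the circular-permutation algebra of minimal
    template regions, k-mer screening of transcript sets, an affine-gap
    Smith-Waterman aligner with BLASTN-style scoring for all-to-all
    cross-species candidate intersection and ortholog extension, inference
    of template domains and the telomere motif they encode, annotation of
    conserved TR gene architecture (template domain, G/C/AT-rich regions,
    TATA and USE promoter elements, Pol III terminator), and computational
    analysis of TRAP products and TRF telomere-length profiles. Includes a
    seeded synthetic-data generator that plants divergent TR ortholog
    families among decoy transcripts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
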