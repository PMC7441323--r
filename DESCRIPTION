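Package: trgscreen
Title: Phylum-Aware Screening for Taxonomically Restricted Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects lineage-specific (taxonomically restricted) genes in a
    focal proteome by presence/absence homology filtering across a clade:
    a candidate must be detectable in at least one genome of every ingroup
    phylum but in no outgroup genome or extra-clade reference entry, with a
    translated-search rescue round that recovers homologs missed by genome
    annotation. Includes a desk-scale local-alignment search engine with
    Karlin-Altschul E-value statistics, a center-star ortholog aligner with
    per-column conservation profiling to classify candidates as fully novel
    proteins or chimeras of an ancient domain and a clade-specific motif,
    and a synthetic clade-proteome simulator with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    ape,
    yaml,
    jsonlite,
    rlang,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
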