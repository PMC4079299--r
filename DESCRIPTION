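Package: retroscope
Title: Endogenous Retrovirus Tag Classification and Host-Gene Association
    from Short-Read Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies human endogenous retrovirus (HERV) expression from
    short single-end sequencing tags. Tags are triaged hierarchically against
    a labeled reference universe (rRNA, host transcriptome, nuclear genome,
    mitochondrial DNA, microbial, HERV) with a seed-and-extend Hamming
    aligner, assigned unambiguously to HERV families with an explicit
    ambiguity margin, and summarized as family tag frequencies and
    length-normalized env/gag-pol/LTR region frequencies. A host-gene
    association stage screens a globally normalized count matrix against
    HERV-K env abundance (detection filter, Pearson r-squared threshold,
    clinical fold-change filter) and tests the surviving gene set for term
    overrepresentation with a hypergeometric test under Benjamini-Hochberg
    control. A seeded synthetic-data generator produces reference sets, tag
    FASTQs, cohort count matrices and ground truth so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
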