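Package: lncvine
Title: Identification and Regulatory Annotation of Plant Long Non-Coding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully tested re-implementation of a grapevine
    (Vitis vinifera) long non-coding RNA (lncRNA) analysis workflow:
    identification of lncRNA candidates from assembled transcripts via
    length, six-frame open-reading-frame, coding-potential-score, and
    protein-homology filters; genomic placement and class-code
    classification against reference gene models; differential-expression
    filtering, abundance binning, and a tissue/developmental-stage
    specificity index; co-expression-based functional annotation with
    partner sets of messenger RNAs, transcription factors, and organelle
    coding sequences; and miRNA interaction calling covering target
    sites, hairpin precursors, and endogenous target mimics. A synthetic
    study generator emits a self-consistent data bundle with a
    ground-truth manifest so the whole pipeline is exercisable and
    verifiable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    limma,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
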