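Package: grnctx
Title: Gene Regulatory Network Contextualization and Regulator Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers transcriptional regulators of an inducible gene under a
    stimulus by combining a weight-matrix (PWM) scan of promoter windows with
    a signed literature network, contextualizing the merged network against
    booleanized two-condition differential-expression phenotypes using a
    synchronous Boolean framework searched with a genetic algorithm, and
    ranking candidate regulators by a simple-path essentiality metric. A
    synthetic-data module generates promoters with planted binding sites,
    signed stimulus cascades and two-condition expression matrices with
    planted differentially expressed genes, so the whole pipeline is testable
    end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
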