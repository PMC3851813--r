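Package: pwmjaccard
Title: Jaccard Similarity and Distance for Transcription Factor Binding Site Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Compares transcription factor binding site (TFBS) models, each a
    position weight matrix (PWM) together with a score threshold, by the
    Jaccard similarity of the word sets they recognize under an i.i.d.
    background. Provides exact P-value and threshold computation for
    discretized PWMs by dynamic programming, a joint two-matrix score-pair
    dynamic program with suffix-bound pruning, optimal alignment over all
    shifts and both strand orientations, the resulting distance metric,
    two-pass scanning of PWM collections, and UPGMA clustering of motif
    collections with newick export. Includes a seeded synthetic PWM
    generator so the whole pipeline is testable without external motif
    databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
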