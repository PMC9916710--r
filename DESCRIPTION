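Package: metasem
Title: Gene Regulatory Network Inference from Single-Cell Expression by
    Meta-Learning over a Structural Equation Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers directed, weighted gene regulatory networks (GRNs) from
    single-cell RNA-seq expression matrices. A structural equation model (SEM)
    adjacency matrix is embedded as a trainable layer between an encoder and a
    meta-decoder; the pair is trained with bi-level (one-step gradient probe)
    optimization so that each gene's pseudo-label is reconstructed from the
    features of its candidate regulators. Includes a linear-SEM expression
    simulator with scRNA-seq-like dropout, BEELINE-style edge-ranking metrics
    (early precision ratio, AUPR, AUROC), regulator-weight extraction,
    cross-network correlation, and a command-line interface covering the
    simulate/preprocess/train/evaluate pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
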