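Package: rbohost
Title: Phage-Host Prediction from Ranked Similarity Lists via Rank-Biased Overlap
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts phage-host relationships by comparing ranked lists of
    prokaryotic species derived from sequence similarity searches. BLAST
    tabular or Mash distance results for a virus and for each candidate host
    against a shared reference database are collapsed into tie-aware ranked
    lists of species, and each virus-host pair is scored with a rank-biased
    overlap (RBO) measure that weights agreement at top ranks most heavily
    (the Phirbo approach). Includes the full benchmark protocol (top-score
    host calls with tie semantics, taxonomic-level accuracy, ROC/AUC,
    stepwise AUPR, F1-maximizing thresholds), a synthetic planted-host
    universe generator, and random contig subsampling for robustness
    experiments on incomplete viral sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    parallel
Config/testthat/edition: 3
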