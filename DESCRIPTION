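Package: mircor
Title: Integrative miRNA-mRNA Interactome Inference from Paired Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers context-specific miRNA-mRNA regulatory interactions from
    paired case/control expression profiles. Counts are normalized by
    median-of-ratios size factors and log2-transformed, features are tested
    for differential expression with an empirical-Bayes moderated t-statistic
    (optionally with a mean-variance trend), all differentially expressed
    miRNA x mRNA pairs are scored by expression correlation with
    Benjamini-Hochberg control over the full pair universe, and negatively
    correlated significant pairs are intersected with target-prediction
    databases to yield a ranked interaction table, per-feature target
    summaries, a bipartite network export, and hypergeometric target-set
    enrichment. A synthetic-data generator with planted differential
    expression and planted negative regulator-target coupling provides ground
    truth for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    DESeq2,
    optparse
Config/testthat/edition: 3
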