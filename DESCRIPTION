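Package: metabodnm
Title: Paired Metabolomic Networks and Dynamic Network Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired (two-condition, within-subject)
    untargeted metabolomics: moderated paired t-tests with empirical-Bayes
    variance shrinkage and Benjamini-Hochberg adjustment, multilevel PLS-DA,
    higher-order SVD of the metabolite x individual x condition tensor,
    per-condition mutual-information networks with data-processing-inequality
    pruning, leading-eigenvector modularity partitioning, eigenvector
    centrality, and identification of a dynamic network marker (DNM) module
    from centrality, centrality change, between-individual coefficient of
    variation and modularity contribution. Includes a synthetic
    paired-metabolome generator with planted differential expression and a
    planted DNM module for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
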