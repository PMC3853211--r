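Package: modnetr
Title: Condition-Specific Transcriptional Module Network Inference
Version: 0.1.0
Authors@R: person("Module Network", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Infers condition-specific transcriptional module networks from
    normalized gene expression data. Provides feature selection with a
    moderated t-test and a clustering-based evaluation grid, ensemble
    Gibbs-sampling Bayesian clustering of genes into co-expression modules
    with spectral consensus tightening, assignment and ranking of candidate
    transcription-factor regulators by a regulatory-program score and by
    regulatory impact factors, module significance scoring with knee-point
    selection of best modules, aggregation of condition-specific regulator
    to target networks with overlap analysis, hypergeometric term enrichment
    with Benjamini-Hochberg control, Cytoscape-compatible export, and a
    synthetic data generator with planted modules and regulators for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
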