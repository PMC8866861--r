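Package: saltsplit
Title: Decomposition of Salinity-Stress Transcriptomes into Salt-Specific
    and Osmotic Responses
Version: 0.1.0
Authors@R:
    person("saltsplit", "maintainers", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools to separate the ionic (salt-specific) and osmotic
    components of a salinity-stress transcriptome from a two-arm dose
    series (NaCl versus iso-osmolar sorbitol). Implements the full
    analysis chain: per-sample quantile normalization, per-gene z-score
    and signed logarithmic scaling; grouped Mann-Whitney tests of
    untreated control against each pooled treatment arm with
    Benjamini-Hochberg adjustment; set-algebra decomposition into
    salt-specific and osmotic gene lists with two-fold-change filtering;
    self-contained Gene Ontology enrichment (OBO parsing, true-path
    annotation propagation, classic hypergeometric Fisher tests and
    elim-style DAG decorrelation); and the accompanying phenotype and
    metabolite group statistics (one-way ANOVA with Fisher LSD compact
    letter displays, Bonferroni-corrected t-tests, Na+/K+ ratios,
    fold-change summaries). A synthetic-data module generates complete
    study bundles with planted ground truth for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
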