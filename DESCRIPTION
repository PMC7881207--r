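Package: tsnetscore
Title: Correlation-Network S- and N-Scores for Tumor Suppressor Genes
Version: 1.0.0
Authors@R:
    person("tsnetscore", "maintainers", email = "tsnetscore@example.org",
           role = c("aut", "cre"))
Description: Scores candidate tumor suppressor (TS) genes by their
    co-expression with differentially expressed (DE) genes in tumor/normal
    cohorts. Implements per-stage differential expression (Welch t +
    Benjamini-Hochberg), a Bonferroni-calibrated Pearson correlation
    threshold T derived from t-distribution quantiles, per-gene S+/S-/S
    correlation-mass scores, shared-node N+/N- network scores on the
    binarized TS-DE bipartite network, ranked score-accumulation profiles,
    and a seeded latent-factor cohort simulator with planted strong/weak TS
    genes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
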