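Package: compbias
Title: Diagnosis and Mitigation of Amino-Acid Compositional Heterogeneity
    in Phylogenomic Supermatrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and reducing amino-acid compositional
    heterogeneity in protein supermatrices, the kind of non-stationarity
    that drives long-branch attraction between unrelated AT-rich lineages.
    Provides per-taxon composition profiling with GARP:FIMNKY ratios and
    UPGMA clustering of compositions, a directional per-site bias statistic
    (zeta) with progressive site stripping, dataset-specific reduced-alphabet
    recoding by minmax chi-square optimization, estimation and collapse of
    empirical amino-acid profile mixtures, a parametric-bootstrap test of
    compositional homogeneity for gene selection, a synthetic two-regime
    data generator, and a pipeline driver tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    seqinr,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
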