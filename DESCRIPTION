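Package: rdnasense
Title: Genome-Wide Expression Consequences of Ribosomal DNA Copy-Number Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing how deletions in the Y-linked ribosomal DNA
    (rDNA) array modulate genome-wide gene expression in Drosophila-style
    two-colour microarray experiments. Provides loess normalisation of
    two-channel intensities, per-contrast differential expression with an
    empirical-Bayes moderated t statistic, Benjamini-Hochberg adjustment and
    permutation-based false discovery rates, Monte-Carlo and hypergeometric
    tests for the overlap of differentially expressed gene sets across
    contrasts and sexes, sliding-window and cytological-division scans for
    positional clustering of affected genes, linear extrapolation of the
    number of small-effect genes escaping detection, flat-category
    over-representation tests, and qPCR delta-Ct estimation of relative rDNA
    copy number. A synthetic-data generator emulates the study design
    (dye-balanced direct comparisons of wild-type against mildly and grossly
    rDNA-deleted Y chromosomes) so every stage is testable without external
    data.
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
    limma,
    jsonlite
Config/testthat/edition: 3
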