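Package: tracksuite
Title: Integrative Analysis of Collections of Genomic Tracks
Version: 0.1.0
Authors@R:
    person("tracksuite", "authors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools for representing, validating and statistically analysing
    collections (suites) of genomic tracks. Implements the GSuite tabular
    collection format, exact base-pair level co-occurrence statistics
    (Jaccard, Forbes, tetrachoric correlation), an integrative statistic
    hierarchy over suites (per-track, whole-suite, cross-suite, binned and
    coverage-depth statistics), structure-preserving Monte Carlo null models,
    and empirical hypothesis tests for five canonical analytical questions on
    track collections. Includes a synthetic-suite generator with known latent
    correlation structure so every statistic and test is verifiable without
    external data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
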