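Package: deprindex
Title: Construction of Regional Socioeconomic Deprivation Indices
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building area-level socioeconomic deprivation indices
    in the style of the German Index of Socioeconomic Deprivation (GISD):
    administrative hierarchies with population weights, harmonization of
    long-format regional indicator panels (deflation and log transforms,
    reporting-break correction, school-reform correction, East-West
    distributional correction, gap carry-forward, random-intercept imputation),
    pooled principal-component weighting per subdimension, factor scoring,
    yearly min-max normalization, population-weighted multi-level aggregation
    and quintile assignment. Includes a synthetic-data generator that emulates
    the German administrative hierarchy and the source data's pathologies, and
    epidemiological linkage analyses: direct age standardization (European
    Standard Population 2013), deprivation-group rate trends, multilevel
    Poisson incidence rate ratios, and deprivation-gradient regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    lme4,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
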