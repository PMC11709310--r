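Package: qcindex
Title: Quality of Care Index Construction from Global Burden of Disease
    Estimates
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a principal-component Quality of Care Index (QCI) from
    Global Burden of Disease (GBD) results-tool style tables of incidence,
    prevalence, deaths, YLLs, YLDs and DALYs.  Four care-quality ratios
    (prevalence/incidence, deaths/incidence, DALYs/prevalence, YLLs/YLDs)
    are standardized and summarised by their first principal component,
    oriented so larger scores mean worse care, and min-max rescaled to a
    0-100 index.  Includes gender disparity ratios with categorical bands,
    country quintile ranking, income/SDI group summaries, change
    statistics between years, a validation bench (reference-index
    correlation and a country-random-intercept model), and a synthetic
    GBD-shaped data generator with retained latent truth for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
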