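Package: fmthgt
Title: Horizontal Gene Transfer Analysis for Faecal Microbiota Transplantation Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects horizontally transferred gene clusters (HTGCs) in
    donor/recipient metagenome summaries from a placebo-controlled faecal
    microbiota transplantation (FMT) time course. Implements high-quality
    MAG filtering, per-participant presence/absence time-course set logic
    with donor species discordance, strain-engraftment-dependent event
    filtering, phylum enrichment with chi-squared post-hoc residual tests
    under Benjamini-Hochberg control, richness-normalised HGT-rate and
    retention mixed models, COG functional profiling with PERMANOVA on
    Bray-Curtis dissimilarities, and a synthetic trial generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    purrr,
    rlang,
    stats,
    utils,
    tools,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
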