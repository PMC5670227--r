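Package: reefbleach
Title: Coral Heat Stress Metrics, Bleaching Surveys and Permutational
    Community Statistics
Version: 0.1.0
Authors@R:
    person("Reef", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for regional coral-bleaching assessments from in situ
    temperature loggers and benthic surveys. Converts sub-daily logger
    records into daily means, thermal anomalies relative to a site's
    maximum monthly mean (MMM), and cumulative Degree Heating Days/Weeks
    (DHD/DHW) under two accumulation rules; scores benthic composition
    and coral health from stratified random point counts over labelled
    quadrat maps and from roving-diver colony tallies; implements the
    community statistics used to compare sites and times (Bray-Curtis
    dissimilarity, one- and two-way PERMANOVA with permutation p-values,
    sequential-Bonferroni pairwise tests, covariance PCA, Pearson
    chi-square); and generates seeded synthetic temperature series and
    DHW-driven bleaching surveys so every pipeline stage is testable
    without field data. A config-driven command line runs each stage or
    a full demonstration pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
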