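Package: egoroster
Title: Egocentric Social Network Measures from Roster Survey Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for managing and analysing egocentric (personal) social
    network data collected with name-generator roster instruments embedded in
    health surveys. Provides a validated data model for ego-alter rosters
    (up to a configurable nomination cap, ordered by closeness), readers and
    writers for long and wide tabular layouts, per-ego network measures
    (network size, network exposure, network homogeneity, tie diversity,
    tie strength, tie multiplexity), grouped sample-level summary tables with
    chi-square and one-way ANOVA comparisons, and a seeded synthetic survey
    generator calibrated to the network structure reported for a sample of
    adults in New Delhi, India, so the full pipeline can be exercised and
    tested without access to restricted survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
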