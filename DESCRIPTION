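Package: reefdive
Title: Vertical Habitat Analysis of Pop-Up Satellite Archival Tag Depth Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the vertical habitat use of reef-associated
    sharks (and other marine predators) from pop-up satellite archival tag
    (PSAT) time-depth records. Reads and validates tag time series, annotates
    records with diel period, lunar illumination and season, identifies
    high-use vertical depth bands by kernel density thresholding, segments
    off-bank excursions deeper than a bathymetric threshold and computes
    per-dive metrics, classifies dives into behavioural types with principal
    components and k-means, fits linear mixed-effects models of mean depth and
    deep-record counts with backward elimination and Tukey contrasts, and
    screens tags for post-release mortality and tag-consumption signatures.
    Includes a behavioural-state track simulator so the full pipeline can be
    exercised and tested without proprietary tag archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lubridate,
    multcomp,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
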