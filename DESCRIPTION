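Package: mascore
Title: Medicine Acceptability Scores from Taste-Assessment Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computing the Medicine Acceptability Score (MAS), a
    net-promoter-style palatability metric for medicinal formulations, from
    hedonic-scale taste-assessment data. Participants are categorised into
    promoters, passives, and detractors around a configurable passives score
    range; the MAS is the percentage of promoters minus the percentage of
    detractors. The package also computes the Willingness-to-Take-Medicine
    Score (WTMS) for binary, forced-choice, and rating-scale willingness
    designs, calibrates the passives range against WTMS by sign and rank
    concordance (Kendall tau-b), transposes a calibrated range across rating
    scales, stratifies cohorts by age, reconstructs integer score
    distributions from published summary statistics, simulates synthetic
    cohorts with known ground truth, and provides a command-line interface
    with CSV/JSON reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
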