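Package: decisionscreen
Title: Decision Phenotyping of Hypocotyl-Root Growth Trade-Offs in Seedling Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for forward-genetic screens that score how
    seedlings arbitrate between hypocotyl and root growth under combined
    light and water-deficit stress. Computes organ responses (dark versus
    dark plus water stress), hypocotyl/root ratio adjustments, and wild-type
    normalized response quotients (RQ) with paired same-plate normalization;
    selects two-group tests by a Shapiro-Wilk/Levene cascade
    (Student/Welch/Mann-Whitney) with Benjamini-Hochberg correction across
    declared families; classifies genotypes into attenuated, normal and
    exaggerated response classes and makes "confused" and decision-mutant
    calls from volcano-plot quadrants; decomposes hypocotyl growth into
    cellular fold-change contributions; and analyses root apical meristem
    zonation from epidermal cell files via a two-component Gaussian mixture
    fitted by EM, rule-based isodiametric and transition cell counts, mature
    cell length, mitotic-index summaries and loess positional curves with
    bootstrap confidence bands. A seeded synthetic-data generator emulates
    the screen's statistical structure (condition-dependent organ lengths,
    plate effects, genotype response classes, zoned cell files) so the full
    pipeline is testable without raw measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    withr,
    car,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    readxl,
    optparse
Config/testthat/edition: 3
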