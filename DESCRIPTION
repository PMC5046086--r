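Package: carbomatrix
Title: Kinetics and Composition Analysis for Organic-Matrix-Regulated
    CaCO3 Precipitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in vitro calcification assays and the
    characterization of biomineral organic matrices. Implements the
    micro-modified pH-drift calcification assay: standard-curve
    calibration of a thymol blue absorbance channel, conversion of
    absorbance to pH and proton concentration, extraction of nucleation
    times and calcification rates, normalization to no-protein controls,
    and the associated statistical treatment (log transforms,
    Brown-Forsythe variance check, one-way ANOVA, Holm-Sidak step-down
    comparisons against a no-protein control). Also provides a pH-stat
    analogue based on cumulative NaOH addition, spectral-count
    percentile-rank enrichment of biomineral matrix versus intestinal
    fluid proteomes, protein isoelectric-point computation and
    acidic-region scanning, Mg:Ca mineral composition from energy
    dispersive spectroscopy, and a synthetic-data module
    (phenomenological logistic curves with planted kinetics and a
    mechanistic carbonate-chemistry simulator) so every stage can be
    exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
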