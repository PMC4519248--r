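Package: finquant
Title: Quantitative Behavioral Phenotyping and Splice-Mutation Genotyping
    for Adult Zebrafish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for adult zebrafish behavioral phenotyping
    from tracked swimming trajectories: triangulated distance and per-second
    instantaneous velocity, speed-activity-profile (SAP) classification with
    body-length-normalized thresholds, water-column (aquatic surface
    respiration) and center-zone (centrophobia) occupancy, opercular
    respiration-rate comparison, and the accompanying nonparametric
    statistical layer (Mann-Whitney, pooled chi-square on SAP distributions,
    exact two-tailed Freeman-Halton Fisher r x c test). A seeded stochastic
    cohort simulator (semi-Markov behavioral states realized as correlated
    random walks in a bounded tank) provides fully reproducible synthetic
    study data. A companion sequence module implements splice-mutation
    genotyping arithmetic: PCR amplicon sizes, T7 endonuclease I fragment
    prediction, alignment-based indel calling with left-alignment
    normalization, splice-donor-disruption classification, and in-frame
    exon-skip transcript outcome prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
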