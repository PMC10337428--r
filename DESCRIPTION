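Package: lifetriage
Title: Anticipatory Triage Ranking for Mass-Casualty Trauma Cohorts
Version: 0.1.0
Authors@R:
    person("Manuel", "Fertig", email = "mfertig@posteo.net", role = c("aut", "cre"))
Description: Dynamic modelling of a trauma patient's expected "LIFE percentage"
    time course from current vital signs (Revised Trauma Score, RTS) and injury
    severity (New Injury Severity Score, NISS), using a modified Boltzmann
    sigmoid. Casualties are ranked by their anticipated survival time without
    treatment instead of being binned into static triage categories. Includes
    the standard START and T-RTS triage comparators, a semisupervised generator
    for artificial trauma cohorts built from a trauma-by-location catalog with
    NISS-banded vital parameter sets, and mixed-data cohort analytics (Gower
    dissimilarity, partitioning-around-medoids clustering with silhouette-based
    model selection, t-SNE embedding, triage cross-tabulation and consensus
    comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    Rtsne,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
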