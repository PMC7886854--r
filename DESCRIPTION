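Package: ensdm
Title: Ensemble Species Distribution Modelling with Convex-Hull
    Pseudo-Absences and Continuous Boyce Index Selection
Version: 0.1.0
Authors@R:
    person("ensdm", "developers", email = "ensdm@example.org", role = c("aut", "cre"))
Description: An ensemble species distribution modelling (SDM) pipeline for
    marine species: occurrence cleaning and gridding, derivation of thermal
    predictor indices, environmental filtration of presences, pseudo-absence
    selection outside restricted convex hulls in environmental space, the
    Non-Parametric Probabilistic Ecological Niche (NPPEN) model plus
    classifier ensemble members, Continuous Boyce Index (CBI) model
    selection under repeated 70/30 cross-validation, delta-change bias
    correction of climate-model fields, multi-GCM/RCP projection of an
    environmental suitability index (ESI), hierarchical geographic
    filtering, and ESI-weighted distributional centroid shifts.  A
    synthetic-world generator supplies gridded fields, a known Gaussian
    niche and occurrence samples so that the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    mgcv,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
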