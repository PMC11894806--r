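Package: sustainz
Title: Subtype and Stage Inference for Regional Brain Atrophy with
    Z-Score Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Event-based modelling of neurodegenerative atrophy from
    regional grey-matter volumes. Provides control-anchored covariate
    harmonization and atrophy-positive z-scoring of regional volumes,
    a z-score event-based mixture model that jointly clusters scans
    into subtypes and stages them along each subtype's event sequence,
    greedy sequence optimization with expectation-maximization
    refinement, Metropolis-Hastings sampling of sequence uncertainty
    (positional variance diagrams), cross-validated selection of the
    number of subtypes (CVIC), maximum-likelihood staging of baseline
    and follow-up scans, longitudinal validation metrics, and
    subtype-pathology enrichment tests. A synthetic-cohort generator
    with known ground truth makes the whole pipeline testable without
    access to source imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
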