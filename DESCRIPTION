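Package: fatiguenet
Title: Symptom/Index Co-Occurrence Networks and Tongue-Pulse Correlation for Fatigue Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds weighted symptom and clinical-index co-occurrence networks
    from binarized physical-examination cohorts, ranks nodes with a weighted
    node-contraction importance statistic (IMC) based on network cohesion,
    extracts core symptom/index subnetworks with Pajek import/export, and
    quantifies the association between tongue colour parameters and pulse
    sphygmogram parameters by canonical correlation analysis.  Ships a
    synthetic-cohort generator (latent-factor Bernoulli symptoms, planted
    canonical correlation between tongue and pulse blocks) so the full
    pipeline is testable without access to clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    tools,
    yaml
Suggests: testthat (>= 3.0.0), withr, jsonlite, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
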