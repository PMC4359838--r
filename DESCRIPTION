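Package: lantree
Title: Latent Tree Analysis of Binary Clinical Manifestation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns latent tree models (hierarchical latent class models) over
    binary symptom/sign matrices by expectation-maximization with a greedy,
    BIC-guided structure search (expansion, adjustment, simplification).
    Interprets each latent variable through mutual-information curves with an
    information-coverage truncation rule, and derives syndrome-factor summaries
    by joint clustering of latent variables that share a factor, including
    sub-syndrome splits for latent variables with more than two states.
    Includes a synthetic-cohort generator with planted latent structure and an
    end-to-end pipeline with deterministic, seed-driven outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
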