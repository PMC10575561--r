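Package: readobs
Title: Ideal-Observer Analysis of Eye Movements in Natural Reading
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the information readers obtain about upcoming words
    from linguistic prediction and parafoveal preview, and measures how much
    of the variation in word skipping and gaze durations each source
    explains. Implements a Bayesian ideal observer of parafoveal word
    identification with an eccentricity-dependent perceptual span,
    contextual priors built from truncated next-word distributions,
    first-pass measure extraction from fixation reports, per-participant
    cross-validated logistic and linear regression, two- and three-way
    partitioning of explained variation, equal-tail bootstrap inference,
    model-derived preview and predictability benefits, and a synthetic
    reading-corpus generator with known ground truth for end-to-end
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
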