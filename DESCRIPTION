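Package: squamorph
Title: Body-Shape Allometry and Axial Morphometrics for Squirrel Ecotypes
Version: 0.1.0
Authors@R: person("Maintainer", "Squamorph", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes skeletal elongation statistics (head-body elongation
    ratio, regional axial elongation indices, geometric-mean body size) from
    specimen-level measurements, fits phylogenetic generalized least squares
    regressions with maximum-likelihood Pagel's lambda, classifies allometry
    against a dimensionless isometric slope using parametric bootstrap
    confidence intervals, performs phylogenetic size correction, and
    decomposes body shape into cranial and axial components with a
    randomized residual permutation procedure (RRPP) and Benjamini-Hochberg
    adjustment. Includes a synthetic-data generator (pure-birth trees,
    Brownian size evolution, ecotype-specific allometric slopes, specimen
    synthesis with measurement noise) so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
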