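Package: dietniche
Title: Diet Indices, Permutation Multivariate Statistics and Isotopic
    Niche Metrics for Pelagic Fish Trophic Ecology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the joint analysis of stomach contents and stable
    isotopes in small pelagic fishes. Computes classical diet indices
    (stomach fullness, frequency of occurrence, numeric and gravimetric
    composition, index of relative importance, Shannon-Wiener diet
    diversity), applies C/N-gated lipid normalization to delta-13C,
    and provides permutation-based multivariate statistics (one-way and
    nested PERMANOVA on Bray-Curtis or Euclidean resemblance matrices,
    PERMDISP, SIMPER, canonical analysis of principal coordinates)
    together with bivariate isotopic-niche geometry (convex-hull area,
    standard ellipse areas with small-sample correction and a Bayesian
    posterior, Layman community metrics, ellipse overlap). A seeded
    synthetic-data generator emulates a multi-species, multi-area survey
    design so every stage of the pipeline can be exercised and validated
    without access to confidential survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
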