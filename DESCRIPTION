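Package: swardiv
Title: Diversity Effects, Community Traits and Water Use in Grass-Legume Mesocosms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pot-scale (mesocosm) grassland diversity
    experiments mixing grasses with a legume. Computes resource-use metrics
    (relative extractable water, daily evapotranspiration from pot weights,
    water-use efficiency, nitrogen yield, community leaf area, growth-rate
    maxima), community-weighted mean traits with trait-specific abundance
    weightings and functional diversity as Rao's quadratic entropy, the
    additive partition of the net diversity effect into complementarity and
    selection effects, proportional deviations of species and functional
    groups from monoculture expectation, and trait-based model selection by
    exhaustive best-subset regression under leave-one-out cross-validation
    with relative importance by ordering-averaged variance decomposition (LMG
    and proportional marginal variance decomposition). A seeded
    synthetic-data generator emulates a 53-pot, six-period grass-legume
    design with injected diversity effects and soil-water dynamics, providing
    ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
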