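Package: sorghumlt
Title: Simulation of the Limited-Transpiration Trait in Grain Sorghum
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale process-based simulation framework for studying the
    limited-transpiration (LT) trait in grain sorghum under water-limited
    environments. Couples a seeded stochastic weather generator emulating the
    US sorghum belt's precipitation/VPD gradient, a layered tipping-bucket
    soil water balance, and a daily crop growth model with hourly vapour
    pressure deficit downscaling and an hourly transpiration cap. Seasons are
    classified into water-stress environment types (well-watered, late,
    mid-season and early drought) by k-medoids clustering of supply/demand
    stress trajectories on centesimal thermal time, and
    trait-by-environment-by-management factorials are analysed with linear
    mixed models, backward AIC model selection and Tukey post-hoc comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    lme4,
    lmerTest,
    emmeans,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
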