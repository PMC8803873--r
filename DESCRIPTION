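Package: mycotraits
Title: Trait-Based Analysis of Fungal Fruiting Communities Across Forest
    Microclimates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing morphological traits of macrofungal fruit
    bodies (size, HSL colour lightness, flesh toughness) in dead-wood
    fruiting communities sampled under contrasting canopy microclimates.
    Builds species trait tables (including lightness extraction from
    photograph pixel samples), assembles presence/absence community
    matrices, computes per-log community trait means with the standard
    transforms, derives standardized effect sizes against an
    independent-swap fixed-marginal null model, and fits nested
    random-effect linear mixed models and binomial GLMs of canopy openness
    on community traits. Includes a synthetic-data generator emulating a
    blocked dead-wood exposure experiment so the full pipeline can be
    exercised and calibrated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    png,
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    picante,
    emmeans,
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
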