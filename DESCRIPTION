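Package: nectarmatch
Title: Plant-Parasitoid Trait Matching, Functional Diversity and
    Multi-Species Parasitism in Sown Flower Strips
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking the functional structure of sown wildflower
    plant communities to the biological control of a multi-species crop-pest
    community by hymenopteran parasitoids.  Implements a mechanistic
    plant-parasitoid trait-matching model of nectar accessibility (a
    geometric decision tree over flower opening, corolla height, nectar
    depth, nectar tube diameter and insect head and proboscis dimensions),
    cover-weighted nectar-resource covariates, mixed-trait Gower
    dissimilarity with functional dispersion (FDis) and Rao quadratic
    entropy, binomial and Poisson mixed models with a single random
    intercept, all-subsets AIC multimodel inference with conditional model
    averaging and Akaike-weight importance, a neutral randomization model
    validating the trait-matching covariate, the multi-threshold
    multi-species parasitism statistic, and a synthetic-data generator
    emulating a replicated flower-strip field design so that the full
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    car,
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
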