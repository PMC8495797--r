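Package: thermhab
Title: Thermal Habitat Models for Demersal Fish from Trawl-Survey and
    Laboratory Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and validates thermal habitat models for demersal
    marine fish in the style used for Mid-Atlantic Bight black sea bass
    analyses: generates synthetic trawl-survey presence-absence data and
    gridded bottom-temperature worlds, bias-corrects modelled bottom
    temperature against a depth-resolved decadal-monthly climatology,
    fits penalized-spline thermal response curves (binomial presence-
    absence and Poisson-family aerobic scope), extracts thermal
    descriptors (deviance explained, thermal optimum, positive log-odds
    range), validates with random Monte-Carlo and rolling year-block
    cross-validation under AUC plus a decile habitat-quality-ranking
    scheme, and projects scaled responses onto seasonal temperature
    fields as habitat-quality maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
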