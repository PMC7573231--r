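Package: sealmito
Title: High-Resolution Respirometry and Fasting Bioenergetics for Molting Seals
Version: 1.0.0
Authors@R: person("sealmito", "developers", email = "sealmito@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for substrate-uncoupler-inhibitor titration
    (SUIT) high-resolution respirometry of permeabilized skeletal muscle,
    and a mass-loss bioenergetic model of fasting metabolism in molting
    phocid seals. Converts annotated oxygen-concentration traces into
    quality-controlled respiratory-state fluxes (leak, OXPHOS, ETS, complex
    I and II), OXPHOS-anchored standardization, flux control ratios, and
    paired pre/post comparisons; apportions fasting mass loss into tissue
    components and energy equivalents; extrapolates whole-muscle leak
    respiratory capacity; and scores gene-set enrichment with the Fisher
    exact test, Benjamini-Hochberg adjustment, and a rank-deviation
    combined score. Ships seeded synthetic-data generators for traces,
    cohorts and differential-expression tables so the full pipeline is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
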