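Package: mpquant
Title: Quantitative Analysis of Micropatterned Stem Cell Colonies and
    Beating Cardiac Microtissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for geometrically confined (micropatterned)
    human pluripotent stem cell colonies and the beating cardiac microtissues
    they give rise to. Provides persistent-random-walk analysis of single-cell
    migration tracks (overlapping-interval mean-square displacement, nonlinear
    model fitting for persistence time and motility coefficient, biased/random
    classification), spatial patterning statistics on circular colonies
    (annulus density maps, marker-positive fractions, nucleus shape index,
    spatial density ratio, two-term power profile fits), and video-based
    contraction quantification of beating tissue (block-matching motion
    estimation, motion waveforms, beat frequency and contraction velocity).
    Includes synthetic-data generators with known ground truth for all three
    input classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    tiff,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
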