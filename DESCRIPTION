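Package: sphscreen
Title: Plate-Based Analysis of COPAS Synapto-pHluorin RNAi Screens
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for whole-genome RNAi screens that read out
    synaptic-vesicle cycling with a synapto-pHluorin (SpH) reporter on a
    COPAS large-particle sorter. Computes per-worm size-normalized relative
    fluorescent signals (RFS), per-well medians, plate-wise robust Z-scores
    (median/MAD), replicate repeatability and sterile-well quality control,
    and multi-round hit calling (distribution tails, one-tailed t-test
    validation against in-plate empty-vector controls, and cytoplasmic-GFP
    counterscreen exclusion). Includes a synthetic screen generator with
    planted effects for end-to-end validation, plus endpoint analytics for
    aldicarb/levamisole paralysis time courses, locomotion trajectories and
    delta-Ct relative expression.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
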