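Package: loopscope
Title: Quantification of DNA Loop Extrusion from Single-Molecule Kymographs
Version: 0.1.0
Authors@R:
    person("loopscope", "developers", email = "loopscope@example.org",
           role = c("aut", "cre"))
Description: Analysis of single-molecule fluorescence experiments in which a
    loop-extruding factor reels DNA into a growing loop on a doubly tethered
    lambda-DNA strand. Converts movies of dye-stained DNA into kymographs,
    segments each time point into loop and flanking regions by Gaussian peak
    fitting, converts intensities to kilobases, and derives per-event extrusion
    rates, worm-like-chain stall forces, extrusion symmetry scores and loop
    displacements, plus population-level looping probabilities with exact
    binomial condition comparisons. Includes a synthetic kymograph simulator
    with tension-dependent extrusion kinetics and full ground truth, so the
    entire pipeline is testable without raw movies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
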