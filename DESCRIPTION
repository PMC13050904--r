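Package: orscreen
Title: Quantification and Combinatorial-Coding Analysis of Odorant Receptor
    Hydrocarbon Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deorphanization screens of ant odorant receptors
    expressed heterologously in Drosophila olfactory neurons and probed with
    cuticular hydrocarbon panels by single-sensillum recording. Provides a
    seeded Poisson spike-train simulator with known ground truth, windowed
    spike-count quantification into solvent-corrected delta spikes/s, tuning
    classification (narrow, broad, intermediate, inhibited, non-responder)
    against a firing-rate threshold, Hill-model dose-response fitting, and
    expression-weighted combinatorial-coding summaries (per-subfamily sums,
    per-hydrocarbon means, FPKM-weighted receptivity, hydrocarbon rankings).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
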