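Package: dyadscope
Title: Multimodal Quantification of Parent-Infant Dyadic Interaction
Version: 0.1.0
Authors@R:
    person("Marin", "Delacroix", email = "marin.delacroix@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying parent-infant dyadic interaction from
    dual depth-sensor recordings of tabletop play sessions. Provides
    spatial calibration of two sensors from chessboard correspondences
    (rigid roto-translation), clap-based temporal synchronisation,
    skeleton stream labelling, outlier suppression, fusion and smoothing,
    a suite of proximity, orientation, movement-contribution and
    hand-contact features, energy-based voice activity detection with
    speaker attribution and speech-turn counting, aggregation of Coding
    Interactive Behavior (CIB) item codes into the eight composite
    subscores, and a fully scripted synthetic dyad recording generator
    with ground truth so the whole pipeline is testable without hardware
    or clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
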