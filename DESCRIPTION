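Package: okncouple
Title: Decoding Bistable Percepts from Optokinetic Nystagmus and
    Quantifying Audiovisual Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying moment-by-moment coupling between visual and
    auditory perceptual multistability. Simulates complete experimental
    sessions (coupled bistable percept traces, noisy button reports, sawtooth
    optokinetic-nystagmus gaze traces with blinks, and disambiguated
    catch-trial tails), segments gaze traces into slow and fast OKN phases,
    extracts time-lagged sliding-window eye-movement features, trains and
    evaluates linear support-vector-machine percept decoders under a
    block-role permutation scheme with class-adjusted (balanced) accuracy,
    and quantifies audio-visual percept consistency together with
    theoretical and expected bounds derived from percept asymmetry,
    decoding accuracy and reporting accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    e1071,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
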