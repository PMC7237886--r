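Package: oriplast
Title: Orientation Tuning, Population Decoding and Behavioral Analysis for
    Chronic Two-Photon Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for chronic two-photon calcium
    imaging of visual cortex during repetitive visual stimulation and rewarded
    virtual-reality behavior. Computes dF/F0 from raw fluorescence traces,
    baseline-corrected trial responses, orientation selectivity via the
    circular-variance resultant vector with a two-criterion selectivity call,
    reliability, pre/post selectivity indices, population orientation shift and
    pre/post cell-fate tracking; population template-matching and single-neuron
    Bayesian maximum-likelihood decoders with d-prime discriminability;
    locomotion segmentation and modulation index; licking success rate and a
    permutation-based spatial modulation index; reward-responsive and
    corridor-responsive neuron classification. Includes a synthetic-session
    generator with known ground truth for validation and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
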