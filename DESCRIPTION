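Package: spikeboot
Title: Bootstrap Classification of Drug-Evoked Spike-Train Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in vivo spike-train recordings of midbrain
    dopamine neurons around intravenous drug injections. Estimates windowed
    firing rates, classifies each neuron as activated, inhibited or
    non-responsive with an interspike-interval shuffle bootstrap, quantifies
    cross-drug polarity concordance with a pooled-surrogate permutation test,
    screens putative dopamine neurons from waveform features, assesses
    optogenetic tagging, and detects postsynaptic currents by template
    matching. Includes generators for synthetic spike trains, neuron
    populations and current traces so that every stage can be validated
    against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
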