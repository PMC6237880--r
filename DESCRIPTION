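Package: hippoctx
Title: Contextual Gating of Associative Memory in a Rate-Coded
    Entorhinal-Hippocampal Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for context-dependent associative memory in the
    entorhinal-hippocampal system. Implements a rate-coded point-neuron
    network (lateral entorhinal cortex, dentate gyrus, CA3, CA1) with
    shunting membrane dynamics, k-winners-take-all inhibition, theta-phase
    encoding/retrieval scheduling, and mixed Hebbian/contrastive-Hebbian
    plasticity. Top-down contextual control is modeled as an excitability
    bias over ensembles of dentate gyrus granule cells; removing the bias
    emulates prefrontal-cortex inactivation. Includes generators for odor
    discrimination stimuli, protocol runners for five behavioral
    inactivation experiments (context-guided retrieval, concurrent and
    blocked acquisition, proactive-interference list learning), prediction
    variants (no pre-training, dentate sparseness sweeps, mossy-fiber
    lesion), and summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
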