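Package: cuneate
Title: Self-Stabilizing Synaptic Learning in a Cuneate Nucleus Neuron Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based simulation of cuneate nucleus projection
    neurons: an exponential integrate-and-fire membrane with low-threshold
    calcium (LVA) and calcium-dependent potassium (CAP) intermediate
    dynamics, calcium-gated Hebbian plasticity of 80 primary-afferent
    synapses with dual homeostatic controls (excitatory weight scaling and
    inhibitory set-point adaptation), a bionic-fingertip spike encoder
    built on the Izhikevich neuron, learning protocols, and analysis
    metrics (Victor-Purpura spike-train distance, response correlation,
    classical MDS of weight landscapes, l2/l1 sparseness) together with a
    Nelder-Mead harness for fitting the intermediate dynamics to voltage
    traces.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
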