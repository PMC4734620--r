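Package: dfcnet
Title: Delayed Feedback Control of Oscillations in Spiking Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and mean-field analysis of closed-loop delayed
    feedback control (DFC) in sparse recurrent networks of leaky
    integrate-and-fire neurons. Provides a fast compiled network simulator
    with alpha-function synapses, transmission delays and a common injected
    control current; Pyragas-style direct, differential and enhancing
    feedback controllers driven by the delayed population rate; linear
    response theory for the noisy LIF neuron based on confluent
    hypergeometric functions, with characteristic-equation root finding,
    critical-coupling computation and (gain, delay) stability landscapes;
    and spike-train metrics (Fano factor, interspike-interval CV,
    oscillation index, pulse-packet ROC/AUC, multivariate SPIKE-distance)
    used to quantify recovery of network function under control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    pracma,
    jsonlite,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    patchwork,
    withr
Config/testthat/edition: 3
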