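Package: ca1pac
Title: Theta-Gamma Phase-Amplitude Coupling in a Reduced CA1 Microcircuit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a reduced hippocampal CA1 microcircuit of pyramidal
    (PYR), parvalbumin basket (PVBC) and oriens-lacunosum/moleculare (OLM)
    cells built from adaptive conductance-based integrate-and-fire neurons
    coupled by event-driven Tsodyks-Markram short-term plasticity synapses,
    driven by Poisson Schaffer-collateral input. Provides the full
    oscillation-analysis toolchain used to characterise the emergent
    theta-nested slow-gamma activity: population rate binning, Welch power
    spectra, spectrograms, phase-amplitude coupling comodulograms with
    surrogate statistics, theta-cycle averaging, and theta/gamma band-power
    covariation, together with synthetic signal and spike-train generators
    with known coupling structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    yaml,
    jsonlite,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
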