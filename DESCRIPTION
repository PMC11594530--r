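Package: blafear
Title: Biophysical Model of Fear Learning in the Basolateral Amygdala
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based (Hodgkin-Huxley) network model of the
    basolateral amygdala fear-conditioning circuit: VIP, SOM and PV
    interneurons plus excitatory projection neurons, GABAa/AMPA synaptic
    kinetics, depression-dominated spike-timing-dependent plasticity on the
    CS-to-fear pathway, Poisson conditioned/unconditioned stimulus drive,
    fourth-order Runge-Kutta integration with per-step Gaussian noise, and
    the spectral analysis (LFP proxy, Thomson multitaper spectra, band power,
    rank-sum comparisons) that identifies the low-theta power increase as a
    biomarker of successful fear learning. Includes experiment drivers for
    natural-frequency scans, conditioning runs, interneuron ablations and
    pre/post biomarker comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
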