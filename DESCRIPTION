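Package: nmspool
Title: Forward Neuromusculoskeletal Simulation of a Motoneuron Pool Driving
    Isometric Dorsiflexion Force
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation pipeline from decomposed motor-unit discharge
    times to isometric dorsiflexion force. Quality-filters high-density EMG
    decomposition output, builds the cumulative spike train and a common
    synaptic input as a weighted average of the trapezoidal force target and
    the smoothed pool discharge rate, integrates a 200-neuron reduced
    compartmental motoneuron pool with size-principle recruitment, converts
    pool spiking to fiber-type muscle activation through calcium
    release/reuptake dynamics, and generates force with a lumped Hill-type
    muscle. Includes force-steadiness and spike-train variability metrics
    (steadiest-window STD and CoV, RMSE, R-squared, z-score median
    correlation, t tests), a +/-20 percent ion-channel sensitivity protocol
    over a 37-parameter registry, and a synthetic-data generator emulating
    decomposed experimental recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    yaml,
    knitr
Config/testthat/edition: 3
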