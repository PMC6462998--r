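Package: spikeflow
Title: Spiking Network Model of Dorsal-Stream Motion Processing and Heading Decisions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hierarchical spike-timing model of the dorsal visual pathway
    (retina, LGN/TRN with feedback interneurons, V1, MT, MST, LIP) driven by
    synthetic visual stimuli. Provides generators for random-dot optic-flow
    fields with a displaced focus of expansion and for multi-region drifting
    bar patterns; a difference-of-Gaussians spatiotemporal retinal filter;
    pinwheel orientation/direction map synthesis and Gabor receptive fields;
    explicit connectivity builders for every projection (feedforward,
    lateral, expansion/contraction templates, decision readout); a fast
    fixed-step integrate-and-fire engine (current-based with exponential
    postsynaptic currents, and conductance-based with after-hyperpolarizing
    conductance); and population-vector decoding plus a two-alternative
    left/right heading decision analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    Rcpp,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
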