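Package: nmsleep
Title: Neural-Mass Modelling of Cortical Columns Across the Sleep-Waking Cycle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a conductance-based neural-mass model of one or two
    coupled cortical columns, each with a pyramidal and an inhibitory
    population, across NREM sleep and wakefulness. The sleep-wake switch is
    implemented as an upscaling of the AMPAergic conductance, with GABAergic
    conductances calibrated so that the waking membrane potentials match the
    NREM Up-state targets. Includes a stochastic Heun integrator, local field
    potential synthesis and spectral analysis, Up/Down state segmentation,
    and a cluster-based permutation test used to quantify the propagation of
    an external stimulus between coupled columns as a function of the
    inter-/intra-columnar conductance ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
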