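Package: synaptode
Title: Biophysical Simulation and Fitting of Glutamatergic Synaptic Transmission
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates excitatory synaptic transmission at a glutamatergic
    synapse with a seven-variable ordinary differential equation model: a
    passive two-compartment (soma/dendrite) neuron in current- or
    voltage-clamp, AMPA and NMDA receptor activation with differential
    glutamate sensitivity and voltage-dependent magnesium block,
    two-compartment glutamate diffusion (cleft centre and perisynaptic
    space) with saturable astrocytic EAAT2 uptake, and
    glutamate-concentration-driven short-term facilitation and
    desensitization. Includes a staged Nelder-Mead trace-fitting procedure
    for voltage- and current-clamp recordings, a synthetic patch-clamp
    recording generator, summary metrics (per-pulse amplitudes, decay
    times), plotting helpers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
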