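Package: dropnet
Title: Event-Driven 1D Circuit Analysis of Droplet Microfluidic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design-stage simulation of passive droplet microfluidic networks
    on the one-dimensional hydraulic circuit model. Channels are resistors
    (rectangular-duct formula), droplets add resistance to the channel they
    occupy, and the steady-state flow field is obtained from Kirchhoff-analogue
    node-balance and cycle-pressure equations built on a fundamental cycle
    basis and solved by LU decomposition. An event-driven engine advances
    droplets between flow-state changes, routes them along the highest-flow
    branch, and checks trapping and Laplace-pressure squeeze-through
    objectives. Includes a cascaded trap-and-merge well fixture and
    design-exploration drivers (minimal bypass length, maximal operating
    pressure, cascade loading time), a structured-text network format, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
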