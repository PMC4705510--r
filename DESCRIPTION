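Package: mucosim
Title: Multiscale Agent-Based Simulation of Mucosal Immune Responses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A multiscale simulator of gut mucosal immune responses coupling
    three spatiotemporal scales on a two-dimensional compartmentalized grid:
    stochastic cell agents (bacteria, dendritic cells, CD4+ T cells and
    user-defined generic types) with Brownian and chemotaxis-biased movement
    and contact- or cytokine-driven state transitions; cytokine value layers
    evolved by a discrete diffusion-evaporation rule; and a reduced CD4+ T
    cell differentiation ODE model (Th1/Th17/Treg) solved per cell by an
    embedded adaptive Runge-Kutta integrator. Includes hybrid per-scale
    update frequencies, pluggable ODE solver-instance strategies (singleton,
    per-cell, pool), model inflation for cost benchmarking, four reference
    scenarios, headless PNG snapshots, tab-separated reporting, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
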