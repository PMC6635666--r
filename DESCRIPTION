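Package: macroshift
Title: Regime Shifts Between Floating and Submerged Invasive Macrophytes
    Under Biological Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of a two-species competition model for
    invasive aquatic macrophytes, in which biological-control mortality on
    floating plants interacts with nutrient loading to drive a regime shift
    to submerged plant dominance.  Floating and submerged biomass follow
    coupled ordinary differential equations with nutrient-dependent
    intraspecific competition; water-column nutrients are tied to plant
    biomass by an algebraic closure.  Provides trajectory simulation
    (adaptive Runge-Kutta and fixed-step Euler), dominance-switch event
    detection, equilibrium location and linear stability classification, a
    brute-force grid oracle, bifurcation scans over the biocontrol rate and
    nutrient loading with critical-threshold refinement, bistability
    probing, scenario configuration files, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    grDevices,
    graphics,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
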