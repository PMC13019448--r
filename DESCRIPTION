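Package: bstkit
Title: Construction, Simulation and Global Sensitivity Analysis of
    Biochemical Systems Theory Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, simulating and analyzing power-law
    (S-system) models of biochemical networks in the Biochemical Systems
    Theory (BST) formalism. Models are specified declaratively (a TOML
    dialect, a plain-text BST dialect, or programmatic records) and
    compiled into stoichiometric and kinetic-order matrices. The package
    integrates the resulting ordinary differential equations with
    time-varying pulsed inputs, computes steady states by dynamic
    settling and by the log-linear algebraic solution of classical
    S-systems, and provides native implementations of Morris
    elementary-effects screening and Sobol variance-based sensitivity
    analysis over user-selected model parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
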