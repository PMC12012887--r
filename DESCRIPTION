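Package: layeredIFC
Title: Layered Autocatalytic Integral Feedback Controllers Under Resource
    Competition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Resource-aware modelling and simulation of biomolecular and
    population-level integral feedback control circuits. Implements a
    quasi-steady-state framework for production reactions competing for
    shared cellular resources (zeroth-order, unimolecular and bimolecular
    rate laws with lumped competition gains), minimal and layered
    autocatalytic controller motifs with closed-form set-points,
    ratiometric controller variants, embedded gene-expression and operon
    gene-ratio circuits, and generalized Lotka-Volterra realizations of
    the same controllers in microbial consortia (population control and
    coculture composition control). Includes deterministic ODE simulation
    with scheduled step disturbances, steady-state detection, equilibrium
    finding, local stability analysis and parametric stability-region
    scans, plus a YAML configuration layer with circuit presets and a
    small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
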