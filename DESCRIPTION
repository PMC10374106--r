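Package: rbcflow
Title: Immersed-Boundary Simulation of Red Blood Cell Motion Near
    Endothelial Surface Layers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-dimensional immersed-boundary simulator for the motion of
    red blood cells in plasma near vessel walls shaped by the endothelial
    surface layer (ESL). Solves unsteady Stokes flow in a channel that is
    periodic in the flow direction with no-slip walls, couples elastic cell
    membranes (stretching, bending, area penalty) and tethered wall
    structures to the fluid through regularized delta functions, and models
    wall permeability with a Darcy-law slip velocity. Includes microscopic
    (fiber-bundle) and macroscopic (sinusoidal) wall geometry builders,
    polyline wall import, biconcave cell generators, parameter sweeps with
    phase-offset averaging, and observables such as wall-induced lift and
    drag, cell-free-layer thickness, mean cell velocity, and occupancy
    density maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
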