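Package: gorgflow
Title: Multiscale Flow and Plankton Capture in Gorgonian Cylinder Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the flow of seawater through the branching structures of
    gorgonian corals (sea fans) at three structural levels: branches, polyp
    tentacles and pinnules. Each level is idealized as an infinite periodic
    array of finite-height cylinders, solved as a single unit cell with a
    steady (or time-marched) incompressible laminar flow solver on a graded
    staggered grid. Provides leakiness metrics (gap-flux and line-average),
    parameter sweeps over Reynolds number and gap-to-diameter ratio, an
    idealized polyp-decorated branch geometry, an agent-based plankton
    capture simulation (advection plus Brownian motion, Euler-Maruyama),
    dimensionless-number reports (Reynolds, Peclet, porosity coefficient),
    and analytic flow-field fixtures for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    grDevices,
    graphics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
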