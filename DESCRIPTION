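Package: lbadhesion
Title: Lattice Boltzmann-Immersed Boundary Simulation of Particle
    Adhesion in Capillary Shear Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-dimensional D2Q9 lattice Boltzmann solver (BGK collision,
    Guo forcing, Zou-He velocity walls) coupled to a moving-least-squares
    immersed boundary method and stochastic ligand-receptor adhesive
    dynamics.  Simulates rigid circular and elliptical micro-particles
    interacting with a receptor-coated wall in linear shear flow, classifies
    particle-wall interaction regimens (firm adhesion, rolling, sliding, not
    adhering), builds phase maps over Reynolds number and ligand density, and
    provides closed-form rolling-velocity relations for rectangular
    microfluidic channels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    tibble
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
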