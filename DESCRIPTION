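Package: osteonflow
Title: Poroelastic Osteon and Canalicular Fluid Flow Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Hierarchical poroelastic model of a loaded osteon. Solves the
    harmonic pore-pressure field in a transverse-isotropic poroelastic
    annulus under cyclic axial strain, couples it to oscillatory Stokes flow
    in a canaliculus spanning the osteon wall, and computes canalicular
    fluid flow rate and wall fluid shear stress amplitudes for two outer
    wall boundary cases (elastic restrained and displacement confined).
    Includes parameter sweeps over strain amplitude, loading frequency,
    strain rate, canalicular radius and intrinsic permeability, together
    with independent brute-force oracles (adaptive quadrature, finite
    difference derivatives, a finite-difference boundary value solver and
    closed-form Poiseuille limits) validating every closed-form result.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
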