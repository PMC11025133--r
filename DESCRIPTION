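Package: cgtribo
Title: Coarse-Grained Parametrization, Simulation and Tribology of
    Polyelectrolyte-Surfactant Films
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bottom-up coarse-grained (MARTINI-style) modelling toolkit for
    cationic polysaccharide / anionic surfactant lubricant films on grafted
    biomimetic surfaces.  Fits harmonic bonded parameters from atomistic
    trajectories by Gaussian-moment Boltzmann inversion, builds
    polyelectrolyte chains with a configurable degree of substitution,
    surfactants, polarizable three-site water and grafted surfaces, runs
    desk-scale coarse-grained molecular dynamics with thermostats, SHAKE
    constraints, confinement under constant normal load and wall sliding,
    and implements the corresponding analysis layer: through-film density,
    charge and velocity profiles, film thickness and hydration, surface
    coverages and charge ratios, radius-of-gyration scaling, shear stress
    and friction-law (power-law and extended Amontons) fits.  Synthetic
    trajectory and friction-data generators give every stage a statistically
    controlled test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nortest,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
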