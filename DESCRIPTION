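Package: spinpore
Title: Coarse-Grained Simulation of Rotating Spiky Nanoparticles Perturbing Lipid Bilayers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Solvent-free coarse-grained molecular dynamics of a three-bead
    lipid bilayer interacting with cargo nanoparticles and a rigid, spiky,
    kinematically rotated nanoparticle. Provides system builders, a Langevin
    (BAOAB) integrator with an in-plane weak-coupling barostat for tensionless
    membranes, and estimators for bending stiffness from height-fluctuation
    spectra, area-compressibility modulus from projected-area fluctuations,
    lipid diffusion from mean-square displacement, lipid number-density maps,
    pore areas, and transmembrane penetration counts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
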