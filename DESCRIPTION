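Package: helixmech
Title: Mechanics and Hydration of Double-Stranded DNA from Trajectory Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for double-stranded DNA confined in cylindrical
    nanopores such as single-walled carbon nanotubes. Provides carbon-nanotube
    chirality-to-diameter geometry, a seeded discrete worm-like-chain trajectory
    generator with prescribed persistence length, stretch modulus and torsional
    stiffness, an idealized Watson-Crick duplex builder, multi-model PDB and
    base-pair-step table input/output, per-frame structural observables (RMSD,
    RMSF, geometric hydrogen bonds, non-native contacts), hydration-shell
    counting with axial water density and Boltzmann inversion to a potential of
    mean force, worm-like-chain elasticity estimators with bootstrap errors,
    and generic pairwise Lennard-Jones plus Coulomb interaction energies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, bio3d
Suggests: testthat (>= 3.0.0), jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
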