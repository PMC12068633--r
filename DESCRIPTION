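Package: cgconform
Title: Coarse-Grained Mapping and Conformation Energetics for Surfactant
    Drug-Delivery Micelles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and analysing coarse-grained (CG) models of
    surfactant drug-delivery systems such as the paclitaxel/Cremophor
    EL/ethanol ("Taxol") micelle.  Maps all-atom structures to MARTINI-style
    bead networks by mass-weighted grouping, derives bonded topologies
    (bonds, angles, dihedrals) by ensemble averaging with optional Boltzmann
    inversion, evaluates harmonic/G96/Ryckaert-Bellemans/periodic potential
    terms with shifted Lennard-Jones and Coulomb interactions, and minimises
    conformations by adaptive steepest descent to obtain gauge-free relative
    conformation energies.  Includes ensemble statistics (histograms,
    correlations, RMSD, radii of gyration), trajectory analyses (partial
    density profiles, radial distribution functions, mean-square displacement
    with windowed diffusion fits), formulation arithmetic (molecular weights,
    mole counts, molar and sphere volumes), seeded synthetic-fixture
    generators, and a command-line interface.  Reads and writes GRO, PDB,
    multi-frame XYZ and GROMACS ITP text formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
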