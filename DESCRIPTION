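Package: qtdg
Title: Torsion-Angle Distributions, Fits, and Sampling Tables for
    Quantum-Derived Conformer Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for building and using torsion-angle priors from
    conformer ensembles. Extracts dihedral observations from 3D molecules
    with a hierarchical torsion SMARTS pattern library, builds 5-degree
    circular histograms and wrapped-Gaussian kernel density estimates,
    converts probabilities to relative energies by Boltzmann inversion,
    fits distributions with fixed-phase (ETKDG-style) and free-phase
    cosine series and with wrapped Gaussian mixtures, and turns fitted
    densities into inverse-CDF sampling tables for torsion driving
    (QTDG-style sampling). Also provides conformer-ensemble preprocessing
    (largest-fragment stripping, InChI identity checks, energy windows)
    and geometry-comparison statistics (minimum heavy-atom RMSD by Kabsch
    superposition, radius of gyration, rotatable-bond regression).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
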