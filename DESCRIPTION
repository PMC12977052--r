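Package: torsionpef
Title: Ensemble-Derived Tabulated Dihedral Potentials and NOE Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts a scored protein conformational ensemble (multi-model
    PDB plus per-model scores in the Rosetta convention) into per-torsion,
    temperature-scaled potential energy functions by Boltzmann inversion of
    score-weighted circular kernel density estimates of the backbone phi/psi
    distributions. Exports the potentials as tabulated molecular-dynamics
    dihedral tables (XVG-style) together with a patched GROMACS-dialect
    topology in which native backbone torsion terms are replaced by the
    tabulated ones. Companion tools reinsert nonprotein components into a
    model by Kabsch superposition onto a reference complex, validate
    ensembles against NOE upper-limit distance restraints (CYANA-style
    dialect) via residue-pair contact matrices and fulfillment ratios, and
    compute backbone RMSD series. A synthetic-fixture generator samples
    von Mises torsion ensembles with score/likelihood coupling so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
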