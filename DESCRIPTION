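Package: DomainContacts
Title: Atomic Bond Classification and Domain Interaction Calling in
    Protein Structures
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and classifies atomic bonds (covalent, electrostatic,
    hydrogen, van der Waals) between protein family domains and between
    domains and small-molecule ligands in 3D structures. Parses legacy PDB
    coordinate files, resolves domain-region annotations onto structure
    residues with E-value based overlap filtering, identifies ligands from
    HETATM records by solvent/nucleic-acid/modified-residue exclusion
    rules, and aggregates atomic bonds into domain-domain and
    domain-ligand interaction calls with residue-level interface detail.
    Includes a synthetic-structure generator for engineered bond
    geometries and a command-line pipeline writing tab-separated
    interaction tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
biocViews: StructuralPrediction, Proteomics, DataImport
RoxygenNote: 7.3.3
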