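Package: AbInterface
Title: Interface Characterization of Paired Immunoglobulin Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize the interface between two paired
    immunoglobulin-like domains (CH3-CH3, CH1-CL, VH-VL) from crystal
    structures or frame ensembles. Detects time-resolved interdomain
    contacts classified as hydrogen bonds, salt bridges, hydrophobic and
    van der Waals interactions; coarse-grains contacts onto beta-strand
    and loop elements of the immunoglobulin fold; compares interface
    classes via mean/SEM summaries and normalized difference maps;
    computes a six-measure interdomain orientation coordinate system
    (torsion, four tilt angles, center-of-mass distance) with kernel
    density estimates; per-residue open-book contact scores; and
    interdomain Coulomb interaction energies. Includes a synthetic
    two-domain complex generator with planted orientations and contact
    lifetimes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils-geometry.R'
    'structio.R'
    'elements.R'
    'chem-roles.R'
    'contacts.R'
    'coarse.R'
    'orientation.R'
    'energetics.R'
    'synthetic.R'
    'pipeline.R'
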