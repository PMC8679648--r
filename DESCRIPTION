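Package: orgsil
Title: United-Atom Force-Field Toolkit for Organosilicon Liquids
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds fully parametrized united-atom topologies for
    tetrahedrally substituted organosilicon molecules (alkylsilanes,
    alkoxysilanes, silanols and siloxanes): automatic atom typing, point
    charges with a charge-neutrality closure on silicon, rigid-bond, harmonic
    angle and Ryckaert-Bellemans torsion terms, and Lennard-Jones parameters
    with a per-oxygenated-substituent sigma reduction on silicon. Includes the
    polarization-correction calculus for phase-change and electronic
    properties (liquid dipole from the Onsager continuum, distortion and
    electronic polarization energies, corrected dielectric constants),
    post-processing of molecular dynamics summaries (dipole-fluctuation
    dielectric, Einstein diffusion with finite-size extrapolation),
    experimental-data curation (temperature regression of densities,
    Clausius-Clapeyron vapor-pressure fits, self-solvation free energies from
    vapor pressure), torsion-profile fitting against quantum-chemical energy
    scans, and a response-surface optimizer for Lennard-Jones parameters.
    Topologies are exported in the GROMACS dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
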