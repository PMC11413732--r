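Package: cspland
Type: Package
Title: Rigid-Molecule Crystal Structure Prediction Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale workbench for crystal structure prediction (CSP) of
    small rigid organic molecules. Generates trial crystal packings in the
    common space groups by quasi-random (Halton) sampling of packing
    variables, performs staged rigid-body lattice-energy minimisation with an
    exp-6 (Buckingham) repulsion-dispersion model plus atom-centred
    point-charge/dipole/quadrupole electrostatics (Ewald summation for the
    charge-charge term), removes duplicate minima by simulated powder X-ray
    diffraction screening followed by cluster-based packing comparison, and
    analyses the resulting crystal energy landscapes: energy ranking against
    reference structures, space-group preference statistics, and the relative
    stability of enantiopure versus racemic packings of chiral molecules.
    Includes a committee delta-machine-learning lattice-energy correction on
    atom-centred symmetry-function descriptors with query-by-committee active
    learning, and a synthetic-data module providing reproducible toy
    molecules, planted reference crystals and a smooth stand-in high-level
    energy oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
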