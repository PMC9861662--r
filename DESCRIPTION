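Package: cntglycan
Title: Carboxylated Carbon Nanotube Models and Glycosaminoglycan
    Adsorption Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds atomistic models of zigzag carbon nanotubes
    functionalized with carboxylic-acid or carboxylate groups (with exact
    partial-charge bookkeeping and periodic bonded topology), idealized
    3D models of glucuronic-acid, N-acetyl-glucosamine and
    N-acetyl-galactosamine residues and of hyaluronan and chondroitin
    decamers, and assembles them into periodic simulation boxes with
    counterions at a prescribed ionic strength.  A seeded synthetic
    trajectory generator emulates adsorption/desorption statistics,
    facial orientation and glycosidic-torsion sampling so that the full
    analysis suite -- cylindrical radial density profiles, monolayer
    metrics, orientation-side classification, detachment events,
    geometric hydrogen-bond counting, Lennard-Jones/Coulomb pair-energy
    decomposition, torsional free-energy maps by Boltzmann inversion,
    RMSF and Cremer-Pople ring puckering -- is testable end to end
    without molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
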