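Package: memgroove
Title: Conformational Geometry of Membrane-Anchored Bcl-xL Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the conformational geometry of
    membrane-anchored Bcl-2-family proteins in molecular dynamics
    trajectories: BH3-binding-groove orientation from helix principal axes
    (moment-of-inertia tensor of C-alpha atoms), alpha1-alpha2 loop radius
    of gyration and transmembrane residue positions relative to the lipid
    phosphate planes, transmembrane helix tilt, stationary-interval
    histograms, full-length model assembly from two source structures, and
    ionization/charge bookkeeping for simulation-system composition.
    Includes a rigid-body synthetic-trajectory generator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    graphics,
    stats,
    utils,
    tools,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
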