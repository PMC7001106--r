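Package: memsite
Title: Mapping and Free-Energy Analysis of Lipid Interaction Sites on
    Membrane Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to locate and quantify lipid interaction sites on
    membrane proteins from membrane-plane trajectories: volumetric
    occupancy density maps and connected-component site detection,
    distance-to-site traces, dual-cutoff per-residue contact durations,
    umbrella sampling along a signed in-plane reaction coordinate with
    free-energy reconstruction by the weighted histogram analysis method
    (WHAM), alchemical relative binding free energies by the multistate
    Bennett acceptance ratio (MBAR), and geometric hydrogen-bond and
    ligand-RMSD characterisation.  Includes a Brownian-dynamics surrogate
    membrane with planted Gaussian binding wells of known depth, so every
    estimator can be validated against analytic ground truth at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
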