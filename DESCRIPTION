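Package: mgatekit
Title: Matrix-Gate Network and Symmetry Analysis of Carrier Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory and structure analyses for the matrix-gate (m-gate)
    region of mitochondrial carrier proteins: a triplet-based C3-symmetry
    deviation metric (psi), salt-bridge / hydrogen-bond / guanidinium-stacking
    occupancy networks with intra- vs inter-helical classification, RMSF
    profiles after least-squares superposition, minimum-distance time series,
    and interface gap (crevice) event detection. Includes a synthetic
    toy-carrier trajectory generator with known ground truth (two-state Markov
    contact channels, injectable domain asymmetry, Gaussian positional noise,
    slab solvent) for end-to-end validation, plus PDB / multi-model PDB input
    and output and a declarative analysis configuration.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
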