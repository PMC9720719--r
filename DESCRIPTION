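Package: tetragate
Title: Structural Analysis of Tetrameric Ion-Channel Gating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-simulation structural analysis for homotetrameric ion
    channels such as the cardiac ryanodine receptor (RyR2): reading and
    renumbering multi-chain PDB structures, building chimera tetramers by
    rigid-body superposition and subunit or segment substitution,
    gate-anchored pore-radius profiling with open/closed state calls,
    trajectory RMSD time series and last-N-frame average structures,
    residue-pair heavy-atom contact percent-occupancy analysis with
    intra/inter-subunit classification and pooled count summaries, and
    sequence-proximity scoring of disease-mutation catalogues against
    high-occupancy interface sites.  A synthetic-data module generates toy
    C4-symmetric channels and trajectories with analytically known pore
    radii, contact occupancies and RMSDs, so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
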