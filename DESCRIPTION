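Package: abtraj
Title: Antibody Molecular Dynamics Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of large-scale antibody dynamics in molecular dynamics
    trajectories. Provides rigid-body (Kabsch) superposition, RMSD and
    per-residue RMSF engines with whole-molecule, per-chain, per-domain and
    fragment-local alignment modes, Fab/Fc hinge-angle triplets across the
    CH1-CH2 linker, steady-state window statistics, cross-trajectory
    conformation matching with time-rescaling for implicit versus explicit
    solvent comparison, solvation-box and ion-count arithmetic, and a
    ground-truth synthetic trajectory generator emulating a hinged,
    four-chain Y-shaped immunoglobulin.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
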