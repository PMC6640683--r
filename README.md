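# abtraj — antibody MD trajectory analysis

`abtraj` quantifies large-scale antibody dynamics in molecular dynamics
(MD) trajectories. It is aimed at structural bioinformaticians and
simulators who need to separate two scales of IgG motion — local
per-residue fluctuations inside rigid immunoglobulin domains, and swinging
of whole Fab/Fc regions about the CH1–CH2 hinge linker — and to compare
trajectories run under different solvent models (explicit water vs
implicit/generalized-Born continuum), where conformational sampling speeds
differ by a scalar conversion factor.

## What it computes

- **Rigid-body superposition** (SVD Kabsch with proper-rotation sign
  correction), the primitive under every metric: `best_fit()`,
  `align_trajectory()`.
- **RMSD**, RMSD = sqrt(Σᵢ |rᵢ(t₁) − rᵢ(t₂)|² / N_atoms) after optimal
  superposition, per pair or per frame: `rmsd_pair()`, `rmsd_series()`,
  with whole-molecule, per-chain and per-domain fit modes and steady-state
  `window_stats()`.
- **Per-residue RMSF**, RMSF_k = sqrt(⟨Σ_{i∈k} |rᵢ(t) − ⟨rᵢ⟩_T|² / N_k⟩_T)
  about the iteratively converged mean structure, with fragment-local
  alignment to exclude domain-reorientation inflation: `rmsf_profile()`,
  `mean_structure()`.
- **Fab/Fc hinge angles**: the left/right/top anchor triplets across the
  CH1–CH2 linker (e.g. Asp31/Lys65/Phe442 tips about the Cys225 vertex in
  an IgG), rigid-motion invariant: `angle_series()`, `triplet_angle()`.
- **Implicit↔explicit comparison**: earliest conformation match,
  sampling-speedup factor, time-axis rescaling and grid overlays:
  `match_time()`, `estimate_scale_factor()`, `rescale_time()`,
  `overlay_table()`.
- **System-setup arithmetic**: padded solvation-box dimensions, ion-pair
  counts from ionic strength under two conventions, and composition audits
  of solvated systems: `padded_box()`, `ion_pairs()`, `audit_system()`.
- **A ground-truth synthetic generator**: a four-chain, 12-domain, Y-shaped
  toy antibody with programmed hinge schedules, per-residue Gaussian
  fluctuation amplitudes (optionally ramped at chain termini), and global
  tumbling — so every estimator above is validated by parameter recovery:
  `make_toy_antibody()`, `simulate_trajectory()`.

Structures are read from PDB and trajectories from multi-model PDB or
CHARMM/NAMD DCD (through bio3d); domain maps (fragments, Fab/Fc regions,
anchors) are YAML, with a documented IgG example in
`inst/extdata/igg_1igt_domain_map.yaml`.

## Worked example

Simulate a 100 ns synthetic trajectory whose left Fab sweeps 30° over a
0.3 Å noise floor, then run the standard battery:

```r
library(abtraj)
toy <- make_toy_antibody()
toy$structure
#> md_structure: 116 atoms, 4 chain(s) [ A B C D ]

truth <- ground_truth(
  hinges = list(hinge_program("fab_left",
                              hinge_schedule("linear", from = 0, to = 30))),
  fluct = fluctuation_spec(0.3), seed = 1, dt = 0.5)
traj <- simulate_trajectory(toy$structure, toy$map, truth, 200)
traj
#> md_trajectory: 200 frames x 116 atoms, t = 0.5..100 ns

all_set <- select_atoms(toy$structure, class = "heavy")
window_stats(rmsd_series(traj, 1, all_set), 50, 100)
#> window [50, 100] ns: mean 5.198, sd 1.007 (n = 101)

ang <- angle_series(traj, toy$map)
round(c(ang$left$values[1], rev(ang$left$values)[1]), 1)
#> [1] 125.6  96.2          # the programmed ~30 degree sweep, recovered

prof <- rmsf_profile(traj, region_atoms(toy$structure, toy$map, "fab_right"))
round(mean(prof$rmsf), 2)
#> [1] 0.5                  # sqrt(3) * 0.3 A = 0.52 A expected

# a copy of the trajectory on a 4x compressed clock is matched at T/4
b <- md_trajectory(traj$structure, traj$coords, traj$times / 4)
m <- match_time(frame_coords(traj, 200), b, all_set)
estimate_scale_factor(max(traj$times), m$t_match, m$match_rmsd)
#> scale_fit: 100 ns (reference) / 25 ns (matched) = factor 4 (~4)
```

The steady-state RMSD plateau (5.2 ± 1.0 Å here) reflects the hinge sweep
plus noise; the hinge-angle trace recovers the programmed ramp; the RMSF
recovers the injected amplitude; and the scale-factor estimator recovers a
constructed time compression exactly.

## The analysis workflow

Numbered scripts under `analysis/` (run from the repository root, in
order) carry the full study on synthetic data: `01_simulate.R` generates
three solvent-condition trajectories (explicit-like, implicit-like with
6× faster exploration and C-terminal amplitude ramps, explicit-ions-like),
`02_rmsd.R`–`04_angles.R` run the RMSD/RMSF/angle batteries, `05_compare.R`
recovers the time-conversion factor (~6) by conformation matching and
builds the rescaled overlay, and `06_system_setup.R` does the
solvation-box and ion arithmetic. Tables land under `results/tables/`,
bulky trajectory archives under `scratch/`.

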