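---
title: "Quantifying large-scale antibody dynamics in MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying large-scale antibody dynamics in MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abtraj)
```

## The problem

An IgG antibody is a Y-shaped, four-chain glycoprotein: two Fab arms
(VH+CH1 paired with VL+CL) joined to the Fc stem (paired CH2+CH3) through a
short, flexible CH1–CH2 linker. In molecular dynamics (MD) simulations of
such a molecule, the interesting signal lives at two very different scales:
local per-residue mobility inside essentially rigid domains, and
large-scale swinging of whole Fab/Fc regions about the linker. This package
provides the standard toolbox for separating and quantifying both, plus a
synthetic trajectory generator with recorded ground truth so that every
metric can be validated end to end without cluster-scale MD data.

A second concern it addresses is comparing trajectories run under different
solvent models. Implicit (continuum) solvent reduces the effective
viscosity, so conformational space is explored faster than in explicit
water; overlaying such trajectories requires estimating a time-conversion
factor and rescaling one time axis.

## Metrics

**RMSD.** For two index-matched conformations,

$$\mathrm{RMSD} = \sqrt{\frac{1}{N_\mathrm{atoms}}
  \sum_{i=1}^{N_\mathrm{atoms}} \left| \vec r_i(t_1) - \vec r_i(t_2)\right|^2},$$

evaluated after treating the pair as rigid bodies and overlapping them with
the optimal rotation + translation. The superposition is the SVD-based
Kabsch solution with a sign correction on the smallest singular value, so
the rotation is always proper (no reflections; mirror images do not
superpose to zero). `rmsd_series()` applies this per frame against a
reference (first production frame by default).

**RMSF.** Per residue $k$ with $N_k$ atoms,

$$\mathrm{RMSF}_k = \sqrt{\left\langle \frac{1}{N_k} \sum_{i \in k}
  \left| \vec r_i(t) - \langle \vec r_i \rangle_T \right|^2
  \right\rangle_T},$$

the fluctuation amplitude about the time-averaged position over the aligned
trajectory. Because $\langle \vec r_i \rangle_T$ depends on the alignment,
the mean structure is made well-defined by fixed-point iteration: frames
are aligned to the running mean and the mean recomputed until it shifts by
less than `tol` (default 1e-6 Å, at most 10 iterations; non-convergence
warns and returns the last iterate — expected when the fit set itself
spans a swinging hinge).

**Fragment-local alignment.** If frames are aligned on the whole molecule,
the relative reorientation of rigid domains leaks into both RMSD and RMSF
and inflates them. All fragment metrics therefore fit on the fragment
itself by default (`fit_mode = "local"`); the whole-molecule fit remains
available (`"global"`) precisely to demonstrate the inflation (the
`analysis/03_rmsf.R` contrast table shows an order-of-magnitude effect on a
hinged arm). A related sanity property holds by construction and is tested:
per-domain RMSD with a self-fit never exceeds the whole-molecule-fit RMSD
evaluated on the same atoms.

**Hinge angles.** Large-scale Fab/Fc motion is tracked by three angles
sharing the CH1–CH2 linker anchor as vertex: left = (Fab-left tip, linker,
Fc tip), right = (Fab-right tip, linker, Fc tip), top = (Fab-left tip,
linker, Fab-right tip). Anchors resolve to CA atoms by default (a residue
centroid rule is available). Angles are rigid-motion invariant, so no
alignment is applied; the cosine is clamped to [-1, 1] before the
arc-cosine for floating-point safety at 0°/180°. For a planar molecule
with the Fc ray outside the Fab wedge the three angles sum to exactly
360°; deviations from 360° diagnose out-of-plane motion.

**Cross-trajectory comparison.** `match_time()` finds the earliest time a
trajectory reaches a query conformation, by minimum superposed heavy-atom
RMSD (an explicit objective replacing visual matching; ties resolve to the
earliest frame). `estimate_scale_factor()` converts that into a sampling
speedup factor = reference time / matched time, reported unrounded with a
rounded convenience value; `rescale_time()` multiplies a series' time axis
by the factor, and `overlay_table()` interpolates several series onto a
common grid (linear, never extrapolating).

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| atom class for metrics | `heavy` | crystal inputs lack hydrogens; keeps implicit/explicit systems comparable. `CA`, `backbone`, `all` available. |
| RMSD reference | frame 1 | traces start at 0 at the first production frame. |
| mean-structure `tol`, `max_iter` | 1e-6 Å, 10 | fixed point is reached in 1–3 iterations for quasi-rigid fragments. |
| `dt` when reading trajectories | 0.1 ns/frame | DCD and multi-model PDB carry no absolute time; always set explicitly for real data. |
| anchor rule | `CA` | one atom per anchor residue; centroid optional. |
| window statistics | sample (n−1) sd | honest for small steady-state windows. |
| box padding | 30 Å | minimum solute-to-wall distance for solvation-box arithmetic. |
| ion counting | `volume` convention | `round(c · N_A · V)`; the `water-ratio` convention (`round(c/55.345 · n_waters)`) is offered because deposited systems rarely state which was used, and the audit surfaces discrepancies instead of matching them. |

## The synthetic generator

`make_toy_antibody()` builds a four-chain, 12-domain Y-shaped CA-bead
molecule (optionally 4 atoms/residue to exercise $N_k > 1$): arms at a
construction angle (default 110°), a 10-residue central linker per heavy
chain, planar by default so the hinge-angle closure is exact, with a
lateral wiggle per domain (zeroed at domain ends) that keeps every fragment
non-collinear and therefore superposable.

`simulate_trajectory()` applies, per frame and in this order: (1) rigid
rotation of each hinged region about its pivot anchor by the programmed
schedule (constant, linear ramp, or sinusoid); (2) iid isotropic Gaussian
noise, per-residue amplitude $\sigma_k$ Å per coordinate, optionally ramped
toward a chain terminus to mimic loop unfolding; (3) a global rigid
tumble-and-drift. A single seed expands by a fixed rule (noise: seed+1000,
global motion: seed+2000, ion placement: seed+3000) and fully determines
the output; the `ground_truth` object is attached to the trajectory and
serializable as a JSON sidecar.

The closed-form consequence used throughout testing: for iid isotropic
noise of amplitude $\sigma$ per coordinate, the expected RMSF is
$\sqrt{3}\,\sigma$ (up to a $\sqrt{1 - 1/T}$ finite-sample factor and the
few degrees of freedom absorbed by alignment).

**What the generator does not emulate** — and hence what passing recovery
tests do and do not show about real MD data: there is no force field, no
solvent, no autocorrelation in time (MD fluctuations are strongly
correlated frame-to-frame), no anisotropic or secondary-structure-dependent
mobility, and domains are perfectly rigid. The generator validates the
*analysis* (that the estimators recover known kinematic and statistical
structure), not the *physics*.

## Study conditions in the analysis scripts

The `analysis/` workflow simulates three 100 ns conditions of the toy
molecule, chosen to reproduce the qualitative contrast between solvent
models: an explicit-like run (σ = 0.25 Å, 30° left-Fab sweep over 100 ns,
250 frames), an implicit-like run (σ = 0.35 Å, the same sweep completed in
one sixth of the nominal time and continuing to 180°, C-terminal amplitude
ramps on both heavy chains, 500 frames), and an explicit-ions-like run
(σ = 0.30 Å, fast sweep, no terminal ramps — the stabilized intermediate).
Because the implicit-like hinge program covers the explicit sweep 6× faster,
the ground-truth conversion factor is 6; `analysis/05_compare.R` recovers
it from the trajectories alone via `match_time()`, and the acceptance
script independently recovers a constructed factor-4 compression and
evaluates the worked 100/16.88 ≈ 5.92 ratio. Problem sizes (116–200
residues, 250–2000 frames) were chosen so the full suite exercises every
estimator at Monte-Carlo-meaningful depth while remaining a desk-scale
computation.

## Numerical choices and edge cases

- Superposition requires ≥ 3 non-collinear points; collinearity is detected
  from the second singular value of the centered coordinates (≤ 1e-8
  relative). Degenerate fits error rather than silently returning an
  arbitrary rotation; trajectory-level operations name the offending frame.
- RMSF on a single-frame trajectory is an error, not zero.
- Weighted fits normalize weights to sum 1; all-zero weights error.
- Alternate locations in PDB input resolve to the highest occupancy, ties
  to the first listed. Insertion-coded residues are carried in a separate
  key and excluded from numeric residue-range selection unless explicitly
  listed.
- `which.min` tie-breaking gives the *earliest* matched time in
  `match_time()`, a deliberate bias toward conservative (larger) speedup
  denominators.
- Ion counts round to the nearest integer; with the volume convention at
  0.05 M in a 147×197×196 Å box this gives 171 pairs, and neither
  convention reproduces the 161 pairs reported for deposited systems of
  that size — the audit reports the gap instead of tuning to it.

## Known limitations

- The comparison module fits a single scalar time rescaling; trajectories
  whose exploration speed varies over time (or that take different paths)
  would need curve registration, which is out of scope.
- Chain assignment of the four anchor residues in the shipped IgG example
  map is an assumption documented in the file, not a fact derived from any
  deposited structure; left/right angle labels flip if the Fabs are
  assigned the other way.
- Readers support PDB (ATOM/HETATM/MODEL) and CHARMM/NAMD DCD through
  bio3d; trajectory writing is multi-model PDB only.
- Per-chain RMSF of a chain spanning the hinge mixes arm reorientation into
  the profile even with a chain-local fit; use region/domain fragments when
  that matters.
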