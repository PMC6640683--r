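#!/usr/bin/env Rscript
# Generate the three synthetic solvent-condition trajectories, archive them
# as multi-model PDB + ground-truth sidecars (scratch/), and summarize the
# study conditions in a table.

source("analysis/00_common.R")
ensure_dirs()

st <- study_trajectories()
message("toy IgG: ", n_atoms(st$toy$structure), " residues (CA beads), ",
        length(unique(st$toy$structure$atoms$chain)), " chains")

rows <- list()
for (nm in names(st$trajs)) {
  tr <- st$trajs[[nm]]
  truth <- st$conditions[[nm]]$truth
  write_pdb(tr, file.path(SIM_DIR, paste0(nm, ".pdb")))
  write_ground_truth(truth, file.path(SIM_DIR, paste0(nm, "_truth.json")))
  sched <- truth$hinges[[1]]$schedule
  rows[[nm]] <- data.frame(
    condition = nm, n_frames = n_frames(tr), dt_ns = truth$dt,
    span_ns = max(tr$times), sigma_A = truth$fluct$sigma,
    terminal_ramps = length(truth$fluct$ramps),
    hinge_sweep_deg = sched$to - sched$from, seed = truth$seed)
  message(nm, ": ", n_frames(tr), " frames x ", truth$dt, " ns, sigma ",
          truth$fluct$sigma, " A, left-Fab sweep ", sched$to - sched$from,
          " deg over 100 ns")
}
tab <- do.call(rbind, rows)
write.csv(tab, file.path(RESULTS, "tables", "simulation_summary.csv"),
          row.names = FALSE)
message("ground truth: implicit-style runs sweep 6x the explicit hinge ",
        "angle in the same nominal time (conversion factor 6 by construction)")
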