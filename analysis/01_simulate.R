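#!/usr/bin/env Rscript
# Generate the two synthetic study systems and write them to disk as
# multi-model PDB plus ground-truth JSON. Everything downstream could be
# recomputed from these files alone. The trajectories are large and fully
# regenerable from the seeds in common.R, so they go under scratch/, not
# results/.

source("analysis/common.R")

for (system in c("reference", "perturbed")) {
  out <- file.path("scratch", "datasets", system)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  s <- study_simulation(system)
  write_toy_dataset(s$carrier, s$sim, out)
  gt <- s$sim$ground_truth
  cat(sprintf("%-10s %d atoms, %d frames -> %s\n", system,
              nrow(s$carrier$structure$atoms), n_frames(s$sim$trajectory), out))
  cat(sprintf("  channel on-fractions: %s\n",
              paste(sprintf("%.3f", gt$on_fraction), collapse = ", ")))
  cat(sprintf("  true psi range (noiseless reference): %.3f .. %.3f deg\n",
              min(gt$true_psi$psi_deg), max(gt$true_psi$psi_deg)))
}
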