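#!/usr/bin/env Rscript
# Build the synthetic study systems used by the downstream analyses:
#   A. a 50-residue Gaussian ensemble with planted pairwise correlations
#      {+0.8, -0.6, 0.0} between chosen residue pairs (DCCM ground truth);
#   B/C. two 30-residue systems, each with a planted 6-residue communication
#      chain between distal sites (pathway ground truth), differing in seed
#      the way replicate simulations of the same complex would.
# Everything is written as plain text (PDB / multi-frame XYZ / JSON truth)
# under results/systems/ so later steps consume files, not R objects.

suppressMessages(library(allopath))

seed <- as.integer(Sys.getenv("ALLOPATH_SEED", "1"))
out <- "results/systems"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## System A: correlation-recovery ensemble
R <- diag(50)
R[5, 10] <- R[10, 5] <- 0.8
R[20, 30] <- R[30, 20] <- -0.6
genA <- generate_ensemble(ensemble_spec(50, R, n_frames = 5000, seed = seed))
write_pdb(genA$structure, file.path(out, "sysA_structure.pdb"))
write_xyz(genA$trajectory, file.path(out, "sysA_traj.xyz"))
jsonlite::write_json(
  list(pairs = list(list(i = 5, j = 10, rho = 0.8),
                    list(i = 20, j = 30, rho = -0.6),
                    list(i = 40, j = 45, rho = 0.0))),
  file.path(out, "sysA_truth.json"), auto_unbox = TRUE)

## Systems B and C: planted communication chains (replicates)
chain <- 13:18
for (tag in c("B", "C")) {
  s <- seed + match(tag, c("B", "C"))
  gen <- generate_planted_path(planted_path_spec(chain, rho_on = 0.9, rho_off = 0.2),
                               ensemble_spec(30, n_frames = 3000, seed = s))
  write_pdb(gen$structure, file.path(out, sprintf("sys%s_structure.pdb", tag)))
  write_xyz(gen$trajectory, file.path(out, sprintf("sys%s_traj.xyz", tag)))
  jsonlite::write_json(list(chain = gen$truth, seed = s),
                       file.path(out, sprintf("sys%s_truth.json", tag)),
                       auto_unbox = TRUE)
}

cat("Simulated systems written to", out, "\n")
cat("  A: 50 residues x 5000 frames, planted rho {0.8, -0.6, 0.0}\n")
cat("  B, C: 30 residues x 3000 frames, planted chain",
    paste(range(chain), collapse = "-"), "\n")
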