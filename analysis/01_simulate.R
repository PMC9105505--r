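#!/usr/bin/env Rscript
# Generate the six-construct synthetic study suite: three wild-type-like
# runs whose EF/BG loop separation stays in the closed range, and three
# mutant-like runs (single missense, double missense, region deletion)
# that acquire open-ward ensembles. Writes the planted ground truth per
# construct and a small multi-model PDB excerpt for inspection.

suppressPackageStartupMessages(library(shp2md))
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

specs <- synthetic_construct_suite(n_frames = 6001, seed = 1)
for (nm in names(specs)) {
  tr <- sample_trajectory(specs[[nm]])
  write_ground_truth(tr, file.path("results/sim",
                                   paste0(nm, "_ground_truth.txt")))
  gt <- attr(tr, "ground_truth")
  cat(sprintf("%-16s group=%-6s frames=%d planted cation-pi=%.3f mixture centres=%s\n",
              nm, attr(specs[[nm]], "group"), n_frames(tr),
              gt$cation_pi_fraction,
              paste(vapply(gt$mixture, `[`, numeric(1), 2), collapse = "/")))
}

# a short excerpt (first 10 frames of one run) as a multi-model PDB
tr10 <- sample_trajectory(ensemble_spec(n_frames = 10,
                                        mixture = specs$wt_run1$mixture,
                                        seed = specs$wt_run1$seed))
write_pdb(tr10, "results/sim/wt_run1_first10frames.pdb")
cat("wrote ground-truth sidecars and a 10-frame PDB excerpt under results/sim/\n")
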