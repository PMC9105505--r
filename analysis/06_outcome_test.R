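#!/usr/bin/env Rscript
# Full pipeline run and the outcome statistics: classify each construct as
# closed-retaining or converting from the fitted ensemble masses, then
# compute the hypergeometric probability that all closed retainers are
# exactly the wild-type-like runs.

suppressPackageStartupMessages(library(shp2md))

cfg <- default_run_config(out_dir = "results/pipeline", seed = 1,
                          n_frames = 6001)
summ <- run_pipeline(cfg, quiet = TRUE)

conv <- unlist(summ$converted)
cat("converted (open-ward ensemble mass >", cfg$min_open_mass, "):\n")
for (nm in names(conv))
  cat(sprintf("  %-16s %s (open mass %.3f)\n", nm,
              ifelse(conv[nm], "converted", "retained closed"),
              summ$open_ensemble_mass[[nm]]))
cat(sprintf("hypergeometric outcome p = %.3f\n", summ$hypergeometric_p))
cat("full tables under results/pipeline/ (summary.yaml, *.tsv, run.log)\n")
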