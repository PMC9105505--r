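#!/usr/bin/env Rscript
# Groove (pY peptide-binding cleft) volume: validate the grid estimator on
# the analytic clamp, then average snapshot volumes for every synthetic
# construct over the 3-30 ns window (one snapshot per ns), reproducing the
# closed < mutants ordering.

suppressPackageStartupMessages(library(shp2md))
dir.create("results", showWarnings = FALSE)

cl <- make_clamp_structure(10, capsule_radius = 5)
v <- groove_volume(cl, atom_sel(cl, resno = 67, name = "CA"),
                   atom_sel(cl, resno = 92, name = "CA"),
                   grid_spacing = 0.4, probe_radius = 1.4, capsule_radius = 5)
va <- clamp_analytic_volume(10, 5)
cat(sprintf("clamp check: grid %.1f A^3 vs analytic %.1f A^3 (%.2f%% error)\n",
            v, va, 100 * abs(v - va) / va))

specs <- synthetic_construct_suite(n_frames = 6001, seed = 1)
rows <- lapply(names(specs), function(nm) {
  tr <- sample_trajectory(specs[[nm]])
  res <- volume_series_average(tr, atom_sel(tr, resno = 67, name = "CA"),
                               atom_sel(tr, resno = 92, name = "CA"),
                               window = c(3, 30), stride_ns = 1)
  cat(sprintf("%-16s mean volume %.1f +/- %.1f A^3 (n = %d snapshots)\n",
              nm, res$mean, res$sd, res$n))
  data.frame(construct = nm, group = attr(specs[[nm]], "group"),
             mean_volume_A3 = res$mean, sd_volume_A3 = res$sd, n = res$n)
})
tab <- do.call(rbind, rows)
write.table(tab, "results/groove_volumes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/groove_volumes.tsv\n")
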