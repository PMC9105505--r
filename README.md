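# shp2md

Post-simulation analysis of conformational ensembles of the SHP2 tyrosine
phosphatase, centred on the closed/open transition of its N-SH2 domain.

SHP2 self-inhibits by docking the N-SH2 domain onto its catalytic (PTP)
domain; activation requires phosphotyrosine (pY) peptides to enter the
N-SH2 binding cleft between the EF loop (residues 66–68) and the BG loop
(89–92), which is gated by the domain's *closed* (loops ~8 Å apart) versus
*open* (~15 Å) conformation. The exon-6-encoded region (E6, residues
215–252) bridges the domains in the self-inhibited enzyme, and the loss of
its contact with N-SH2 shifts the domain towards the open state. This
package provides the measurement layer for that kind of study, as a tested
R pipeline that runs on multi-model PDB ensembles and on synthetic
trajectories with planted ground truth:

* **Structure/trajectory I/O** — multi-model PDB reading/writing with
  strict topology checks, named region selections (N-SH2, C-SH2, PTP, E6,
  the D'E/EF/BG/34–40 loops), van der Waals radii.
* **Geometry** — Kabsch superposition (proper rotations only), RMSD series
  against arbitrary references (overall or per-residue), interatomic
  distance series.
* **Interfaces** — residues of one region within a 5-Å heavy-atom
  threshold of another, per-frame minimum-distance heat maps, B-factor
  distance colouring for surface rendering.
* **Surfaces and volumes** — Shrake–Rupley areas (Fibonacci quadrature),
  buried interface area `A = (A_a + A_b − A_complex)/2` on van der Waals
  surfaces, and a grid/flood-fill volume of the groove between the EF and
  BG loops.
* **Ensemble statistics** — sliding-window conformer-fraction curves
  (0.15-nm window), column-synchronised Gaussian deconvolution (shared
  centres/widths, free non-negative per-construct amplitudes), Lys/Tyr
  cation–pi detection (L ≤ 8 Å, θ ≤ 60°), averaged conformers with
  per-residue CA RMSD in the B-factor field, and the hypergeometric
  outcome test (point probability; `1/choose(6,3) = 0.05` for a perfect
  3-of-6 split).
* **Synthetic data** — generators that plant loop-separation mixtures,
  cation–pi contact fractions, domain gaps and groove geometries exactly,
  so every stage is testable without MD engines or downloads.

## Worked example

The `analysis/` directory holds the numbered workflow drivers
(`01_simulate.R` … `06_outcome_test.R`). The heart of it, by hand:

```r
library(shp2md)

# six synthetic constructs: 3 wild-type-like, 3 mutant-like (6001 frames,
# 5 ps spacing, i.e. 0-30 ns)
specs <- synthetic_construct_suite(n_frames = 6001, seed = 1)
curves <- lapply(specs, function(sp) {
  tr <- sample_trajectory(sp)
  ds <- clip_window(distance_series(tr, c("A", 67, "CA"), c("A", 92, "CA")),
                    c(3, 30))              # EF/BG loop separation, 3-30 ns
  fraction_curve(ds)
})
fit_column(curves, K = 3, seed = 1)
```

```
#> <column_fit> K = 3, residual = 0.2695
#>   centers (A): 8.810, 11.936, 13.527
#>   widths  (A): 0.788, 0.861, 0.895
```

The three shared Gaussians are the conformational ensembles: a closed one
near 8.8 Å and two open-ward ones. The per-construct amplitudes (row per
curve) show the wild-type-like runs populating only the closed ensemble
while the mutant-like runs shift into the open ones — e.g. the
region-deletion analogue fits `0.234  0.000  0.464`. Classifying each
construct by its open-ensemble mass and testing the outcome:

```r
summ <- run_pipeline(default_run_config(out_dir = "results/pipeline", seed = 1))
summ$hypergeometric_p
#> [1] 0.05
```

i.e. the probability that all three closed-retainers are exactly the
wild-type runs is 0.05. The same run writes groove-volume averages (28
snapshots over 3–30 ns) ordering closed below the converters
(`936 ± 55 Å³` for a wild-type-like run vs `1132 ± 174 Å³` for the
deletion analogue), cation–pi contact fractions recovering the planted
values (0.397 measured in-window vs 0.400 planted for a wild-type-like
run), interface heat maps, RMSD series and averaged conformers, all as
tab-separated tables plus `summary.yaml` under the output directory.

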