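---
title: "Quantifying the closed/open transition of the SHP2 N-SH2 domain from conformational ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the closed/open transition of the SHP2 N-SH2 domain from conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

SHP2 (gene *PTPN11*) is a tyrosine phosphatase with two tandem SH2 domains
(N-SH2, residues 1–103; C-SH2, 111–213) ahead of the catalytic PTP domain
(253–529). The enzyme self-inhibits by docking the N-SH2 D'E loop (58–62)
into the catalytic pocket. Activation requires a phosphotyrosine (pY)
peptide to bind N-SH2 between its EF loop (66–68) and BG loop (89–92) —
which is only possible when the domain is in its *open* conformation, with
the two loops far apart. In the self-inhibited enzyme the domain sits in
the *closed* conformation with the loops near each other. What stabilises
the closed conformation is the question this package's analyses address:
the exon-6-encoded peptide (E6, residues 215–252) bridges N-SH2, C-SH2 and
PTP, and weakening its contact with the N-SH2 34–40 loop shifts the domain
open.

`shp2md` implements the post-simulation analysis layer of such a study as
a tested, reusable pipeline: given conformational ensembles (multi-model
PDB), it quantifies domain–domain interfaces, buried contact area, the
volume of the pY-binding groove, the distribution of loop-separation
coordinates with a constrained Gaussian deconvolution, cation–pi contact
fractions, averaged conformers, and a hypergeometric test of the study
outcome. Running the molecular dynamics itself (force fields, solvent,
thermostats) and homology model-building are out of scope; the package
starts from recorded conformers.

## The observables and their parameters

**Conformational coordinate.** The closed/open state is read from the
Gly67 Cα – Asn92 Cα distance (EF/BG separation): about 8 Å closed, about
15 Å open in the reference crystal forms. Companion coordinates (Pro38 Cα
– Thr59 Cα, Thr59 N – Tyr62 O, Lys55 O – Tyr66 N, Ser36 Cα – Lys55 Cα)
track the 34–40 and D'E loops and the Lys55/Tyr66 couple.

**Interfaces.** A residue of one region is *interfacial* with another
when its closest heavy atom lies within 5 Å of any heavy atom of the
partner (hydrogens never count). Inter-domain linker residues (104–110,
plus the deletion-boundary residues Gln214/Thr253 where relevant) are
excluded via the `exclude` argument. Heat maps record the per-frame
minimum distances, with a rendering cap (default 10 Å) beyond which a
cell is "absent"; the cap is presentational, only the 5-Å rule is
normative. "Stable" versus "transient" interface membership is not
quantified in the source literature; `interface_residence()` makes it
operational — interfacial in at least half of the analysed frames is
stable — and the cutoff is a parameter.

**Buried area.** The N-SH2/PTP contact area is
`A = (A_NSH2 + A_PTP − A_complex) / 2` computed from *van der Waals*
surfaces, i.e. probe radius 0 — that wording is taken literally, so 0 is
the default; solvent-accessible mode (probe 1.4 Å) is one argument away.
Surfaces come from a Shrake–Rupley quadrature with a deterministic
Fibonacci sphere lattice (default 960 points/atom; two-sphere closed
forms are reproduced within 2%, isolated spheres within 0.5%, and
doubling the lattice moves 50-atom toys by < 1%). Note the lattice is
fixed in the laboratory frame: areas of rotated structures agree only up
to quadrature noise.

**Groove volume.** The pY-binding cleft volume was originally measured
with a desktop tool whose cavity algorithm is not documented; this
package substitutes a declared, reproducible method. The groove envelope
is a capsule of radius `capsule_radius` (default 5 Å) around the axis
joining the CA centroids of the EF and BG mouth selections; the volume
counts grid voxels (default 0.5 Å) inside the envelope, outside all
inflated atom spheres (`vdw + probe`, probe default 1.4 Å — a water-sized
probe defines "open" groove space), and connected to the envelope
boundary by 6-neighbour flood fill, so sealed voids are excluded.
Because the algorithm differs from the original tool's, absolute volumes
are not comparable with the original figures; all conclusions drawn from
it here are ordinal (closed < mutants < open), which the tests check.
The estimator is validated against an exact closed form on a clamp
fixture whose envelope is a spherocylinder minus the mouth-atom balls
(within 5% at 0.4 Å spacing).

**Ensemble deconvolution.** The distribution of a loop-separation
coordinate is summarised as a conformer-fraction curve: the fraction of
frames (normalised per total frames, so disjoint windows sum to 1) whose
value falls in a sliding window of 1.5 Å (0.15 nm). Only the width is
inherited from the study design; the step is a free choice, default
width/5 for smooth curves (tests that rely on exact normalisation use
step = width). Curves from several constructs are deconvolved *jointly*:
one set of K Gaussians whose centres and widths are shared across the
column while amplitudes vary per curve, with non-negative amplitudes
(fractions cannot be negative). Sharing the positional parameters is the
point: it makes amplitudes comparable across constructs as populations of
the *same* ensembles. The optimiser is bounded L-BFGS-B over centres,
widths and amplitudes from 20 seeded multi-starts, centres initialised at
mass quantiles of the pooled curves (order-invariant, so permuting the
curves permutes only the amplitude rows). Non-convergence is flagged on
the returned fit, not thrown. One caveat for sampled (as opposed to
analytically constructed) curves: the sliding window convolves the
underlying density with a 1.5-Å boxcar, biasing fitted widths upward by
roughly `sqrt(w^2/12)` in quadrature while leaving centres unbiased;
recovery tests on centres use sampled data, width-recovery tests use
constructed curves.

**Cation–pi contacts.** A Lys/Tyr cation–pi contact holds in a frame when
L ≤ 8 Å and θ ≤ 60°, where L is the Lys NZ to Tyr ring-centroid distance
and θ the angle between the ring normal and the NZ–centroid segment,
folded into [0°, 90°]. The ring normal is the smallest-eigenvalue
eigenvector of the centred ring-atom covariance — robust to slight
non-planarity, unlike a single cross product. The study's own text states
the L threshold inconsistently (8 Å in the methods, 7 Å in the
corresponding figure); this package defaults to the methods value, makes
the threshold an explicit argument, and emits a note on every call so the
choice is visible in logs.

**Outcome test.** With six simulations of which three are wild-type, the
probability that the three closed-conformation retainers are *exactly*
the wild-type runs is the hypergeometric point probability
`1 / choose(6,3) = 0.05`. The point-probability reading is the default
because it is the one that reproduces that printed value; an upper-tail
option exists but is off by default.

## What the synthetic generator emulates — and what it does not

Every analysis stage is validated on synthetic trajectories with planted
ground truth (`sample_trajectory()`, `make_clamp_structure()`,
`make_two_domain_complex()`). The generator reproduces the
*analysis-facing* features of an MD conformer stream: frames every 5 ps;
a loop-separation coordinate drawn from a prescribed Gaussian mixture and
planted exactly (the mouth CAs are placed at the sampled distance, so the
measured series equals the planted one bit-for-bit); a Lys/Tyr pair in
cation–pi contact in exactly `round(fraction * n)` seeded frames;
isotropic per-residue jitter of stated amplitude; and pseudo-domains with
an exact closest-approach gap and an optional bridging strap emulating
E6. Identical seeds give bit-identical trajectories.

The defaults encode the study conditions: 6001 frames at 5 ps (0–30 ns),
analysis window 3–30 ns, groove snapshots every 1 ns (28 per run), and a
six-construct suite — three wild-type-like runs with closed ensembles
(centres 8.6–9.0 Å, inside the closed range of 8.3–10.4 Å), and three
mutant-like runs that add open-ward ensembles at 11.7, 12.6 and 13.6 Å
with weights growing as the E6 contact is progressively lost (0.55, 0.65,
0.70). Cation–pi fractions are similar for the closed retainers (0.38 to
0.42) and reduced for the deletion analogue (0.25), mirroring the
qualitative contrast reported for those constructs; the exact values are
the package's own choice since none are printed in the source. Mixture
widths (0.6–0.8 Å) are typical loop-distance fluctuations.

What the generator does **not** emulate: physics. There is no energy
function, no correlated collective motion, no solvent, no anharmonicity,
and coordinates other than the planted ones are i.i.d. jitter. Passing
tests therefore demonstrate that the *measurement* layer is correct and
that planted signal of realistic magnitude is recovered — they say
nothing about whether real MD would produce such signal, nor do they
validate force-field choices.

## Classification and the outcome statistic

A construct "retains the closed conformation" when, in the
column-synchronised fit of its loop-separation curve, the Gaussian mass
(amplitude × width) carried by components with centre above
`open_center_cutoff` (default 11 Å, the gap between the closed range and
the lowest mutant ensemble) stays below `min_open_mass` (default 0.2).
On the default suite this classifies the three wild-type-like runs as
retainers and the three mutant-like runs as converters, and the
hypergeometric point probability of that perfect split is 0.05.

## Numerical choices and degenerate inputs

* Kabsch superposition uses SVD with the usual sign correction; a
  reflection is never returned. Collinear selections fall back to the
  degenerate-subspace SVD solution. Fewer than three paired atoms, or
  selections that disagree in atom identity, are errors.
* PDB parsing is strict where silence would corrupt analyses: models with
  differing atom lists, unreadable coordinate fields (reported with line
  numbers) and insertion codes are errors; alternate locations keep the
  highest-occupancy conformer; unknown elements get a 1.70 Å radius with
  a warning. Trajectory time stamps default to frame × 5 ps.
* Coincident atom centres make the surface quadrature ill-defined and are
  an error naming the pair. Coincident mouth centroids (no groove axis)
  are likewise an error.
* `fit_column` requires curves with matching window geometry and
  `K` at most the number of windows; ties in centre ordering cannot occur
  after the final sort because centres are continuous optimiser output.
* All pipeline randomness (generator, fit multi-starts) derives from the
  config seed; outputs are byte-identical across reruns, which the tests
  assert literally.

## Problem sizes used by the tests

The shipped tests run the full pipeline at 1200–1400 frames per construct
(6–7 ns equivalents) with reduced multi-start counts, and the analysis
drivers and acceptance script run the full 6001-frame, 3–30 ns
conditions; both regimes classify the suite identically. Brute-force
oracle comparisons use toys up to 200 atoms, where exact agreement is
required, not approximate.

## Known limitations

* Groove volumes are method-specific (capsule envelope); compare them
  only within this package.
* Fitted widths of sampled curves carry the sliding-window broadening
  described above.
* The interface scan is an exact per-residue vectorised computation, not
  a spatially hashed one; it is sized for per-domain selections
  (thousands of atoms), not whole-proteome sweeps.
* The crystal-structure anchors (the 8.2 Å closed and 14.8 Å open EF/BG
  separations in the reference structures 2SHP and 1AYA) require
  fetching those entries from the RCSB archive; `fetch_pdb()` does so and
  caches, but offline environments cannot run that single check.
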