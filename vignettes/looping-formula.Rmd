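---
title: "Predicting promoter firing from looping distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting promoter firing from looping distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopfire)
```

## The model

`loopfire` predicts the *relative* probability that an active promoter
fires from a single genomic covariate: the distance `l` to the promoter
that can tether it to a transcription factory. Two configurations dominate
the first steps of the firing pathway — the promoter binding a
TF:pol (a transcription-factor:polymerase complex) directly, and the
promoter being held at the factory by a chromatin loop anchored at its
nearest active neighbour. Summing the Boltzmann weights of the two
configurations, with the fractal-globule contact probability
`p(l) ~ a/l` for a confined chromosome, gives

    ptrans(i) ~ b * (1 + c / l(i))

where `b` absorbs TF:pol concentration, promoter number and binding
affinity, and `c = (exp(beta*eps) - 1) * a` absorbs affinity and looping.
`boltzmann_ptrans()` exposes this derivation term by term — the unlooped
weight `n e^(beta eps) (1 - p(l))` and the looped weight
`n e^(2 beta eps) p(l)` — and the package tests verify the algebraic
identity between the two routes to machine precision. Because only ranks
of `ptrans` are ever compared, the partition function `Z` is never needed.

Two variants are provided by `predict_firing()`:

* **1-state**: all promoters share one weight, and `l` is the distance to
  the nearest active promoter of any class. `b` and `c` cancel from the
  rank order, which equals the order of increasing `l`.
* **3-state**: promoters classified from a ChromHMM-style segmentation as
  active genic (state 1), active non-genic (states 4+5) or *other* carry
  weights `b_g`, `b_ng`, `b_o`, and the loop always tethers through the
  nearest *genic* promoter; when no genic partner exists on the
  chromosome, only the unlooped term remains.

## Parameters and defaults

* `c = 86000` bp: the average chromatin loop length measured in HeLa, used
  because loop lengths for the modelled cell types are not known. At
  `l = c` the looped and unlooped configurations have equal weight;
  `loop_weight_ratio()` gives the 10:1 / 1:1 / 1:10 ratios at 8.6, 86 and
  860 kbp. Rank correlations are insensitive to `c` over 3–300 kbp.
* `b_g, b_ng, b_o = 13.1, 3.3, 1`: GRO-seq-derived weight ratios for human
  chromosome 14 in HUVECs. `estimate_state_weights()` recomputes such
  weights from any binned nascent-transcription track as per-state mean
  signal normalised to the *other* class; passing the looping parameters
  divides the `(1 + c/l)` factor out of each promoter's signal first, so
  the weight estimate is not confounded by the distance structure (on
  noiseless synthetic data the inversion is exact).
* Promoter positions are DHS peak midpoints — symmetric and
  deterministic; the overlap rule is any-overlap (≥ 1 bp) with precedence
  genic > non-genic > other when a peak spans several segments. Peaks
  whose midpoints coincide are merged so `l = 0` (where the formula
  diverges) cannot occur. Strand is ignored throughout: the model is
  strandless.

## Evaluation

Predicted ranks are compared against a reference ranking (nascent
transcription, or simulation output) with `evaluate_prediction()`:
Spearman's rho on tie-averaged ranks with the large-sample t
approximation for the p-value (flagged at the 1e-6 threshold; a seeded
permutation option exists for small n), a 10×10 decile confusion matrix
(remainder items deterministically assigned to earlier deciles), and the
decile agreement ratio — same-decile counts over the n/10 expected by
chance, so 10 is a perfect match and 1 is chance. Promoters are scored by
the signal of the 3 kbp bin containing their midpoint, matching the
coarse-graining used for cross-dataset comparison; promoters with zero
signal are kept as bottom ties rather than dropped. The comparison is
promoter-level; a bin-level comparison can be built from
`bin_signal()` directly.

## The synthetic generator

`synth_chromosome()` places promoters by a homogeneous Poisson process
(defaults: 107 Mbp, 2,226 promoters — mean spacing ≈ 48 kbp — split
344:938:944 between genic, non-genic and other, emulating human
chromosome 14 in HUVECs). Positions falling in an occupied 3 kbp signal
bin are re-drawn: promoters sharing a bin are unresolvable at the track's
resolution, and resolvability is what makes the generator/evaluator loop
closed. `synth_signal()` writes `b_state * (1 + c/l_genic)` into each
promoter's bin under multiplicative lognormal noise — a strictly positive,
read-count-like noise model chosen for the synthetic stand-in; it makes
no claim about real GRO-seq error structure. What the closed-loop tests
show is therefore internal consistency (generator, classifier, formula
and evaluator agree, and parameter recovery inverts the generator), not
genome-scale accuracy: real data add mappability artefacts, uneven
backgrounds, promoter-width effects and biological noise that the
generator deliberately omits.

## The polymer model

`run_sim()` is a desk-scale Brownian-dynamics implementation of the
bead-and-spring chromatin model that motivates the formula: 3 kbp = one
30 nm bead (`sigma`), DHS-containing beads are transcription units (TUs)
with shifted-Lennard-Jones affinity for diffusing TF:pol particles
(genic 7.1, non-genic 4.4, other 3.5 kT; acetylated beads 2.7 kT;
cutoff 1.8 sigma; depth normalised exactly to eps via
`lj_norm_factor()`), all other pairs purely repulsive (WCA). TF:pols
switch between binding-competent and inert states at constant rates,
which lets strongly bound particles recycle. Chain mechanics are the
standard Kremer–Grest choices (FENE `K = 30 kT/sigma^2`, `R0 = 1.6
sigma`) with a Kratky–Porod bending stiffness of 3 kT (persistence length
~90 nm), the field's conventional values for chromatin-scale bead-spring
fibres. Confinement is a harmonic
penalty outside an ellipsoid with the 22.24:34.24:41.80 aspect ratio,
scaled by `scaled_semiaxes()` to keep the full model's particle volume
fraction (~0.14) at toy size.

Numerical choices: the integrator is explicit Euler–Maruyama on the
overdamped Langevin equation with friction 1 in reduced units. The
default `dt = 0.001` tau is set by FENE-bond stability under the thermal
noise of the explicit update; trajectory-averaged energies change by less
than 5% when `dt` is halved. A Verlet neighbour list (skin 0.4 sigma,
rebuilt when any particle has moved more than half the skin) keeps the
force loop linear in practice. Three guards make arbitrary starting
configurations safe: an overlap-free serpentine-lattice initial
conformation, a zero-temperature push-off phase with a tight displacement
cap, and a distance floor (`min_d`) under pair-force evaluation. A bond
reaching `R0` aborts with an error naming the bond — the signal that `dt`
is too large for the chosen parameters. All randomness flows through R's
RNG, so a seed makes trajectories bit-identical.

Analysis mirrors the chromosome-scale workflow at toy size:
`residence_ptrans()` estimates firing as the fraction of sampled frames
with an active TF:pol within `rc` of a TU bead ("bound" is not otherwise
defined by the model, so the interaction range is used);
`detect_clusters()` finds single-linkage TF:pol clusters at threshold
`d_cl = rc` (the same scale that defines binding); and
`peripheral_fraction()` reports how many cluster centroids lie outside
the half-volume inner ellipsoid (semiaxes scaled by `2^(-1/3)`), for
which uniform points give exactly one half.

## Problem sizes

The package's simulation experiments run on a 600 kbp toy chromosome
(200 beads, 10 TUs, 10 TF:pols). Rank cross-validation against the
formula uses an equilibration of 10^4 steps and 6×10^4 production steps
sampled every 300; cluster statistics, which need the slower collective
rearrangements to approach steady state, use 4×10^4 and 1.2×10^5 steps.
These sizes resolve the affinity ordering and the emergence of bridging
clusters while keeping a full multi-seed experiment in minutes. They are
two orders of magnitude below the full-chromosome model (35,784 beads, 64
replicates), so quantities tied to that scale — the ~0.6 genome-wide
Spearman correlation against GRO-seq, the 1.82/1.31/1.71 decile agreement
ratios, the 88.5% peripheral cluster fraction — are out of reach by
design; the desk-scale claims are the directional ones the tests assert
(positive simulation-vs-formula rank correlation, clustering above the
no-attraction control, outward bias of cluster centroids).

## Known limitations

Only intra-chromosomal distances enter the formula (no trans contacts),
only the two leading configurations are summed, all TF:pols are one
colour, and a genic tether is assumed for every promoter class however
far the nearest genic promoter is. Absolute firing rates are not
predicted — `Z` is never computed — so only ranks and ratios are
meaningful. In the worked example the 3-state value for promoter r,
3.87 b_ng, follows from the 30 kbp distance to its genic neighbour q —
the geometry the implementation uses for every 3-state loop.
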