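---
title: "Predicting transmembrane helix packing from sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting transmembrane helix packing from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixpack)
```

## The problem

Alpha-helical transmembrane (TM) proteins pack their membrane-spanning
helices into a bundle whose geometry is strongly constrained: all helices
share the membrane normal, so once the topology (the ordered list of helix
residue spans) is known, the packing problem is essentially two-dimensional
— which helices touch, and how each is rotated about its own axis.
helixpack predicts that arrangement from sequence in five stages: lipid
exposure, residue contacts, helix–helix interactions, decoy discrimination,
and construction of a 2-D packing layout.

## Lipid exposure

A TM residue is *lipid exposed* when its side chain faces the bilayer
rather than the protein core. Ground truth comes from per-residue
lipid-contact fractions (the fraction of coarse-grained simulation time a
residue touches lipid); the label is `fraction > 0.5`, strictly.

The classifier is an RBF-kernel SVM over windowed sequence-profile
features: for each TM residue, the 20 profile columns of the 7 residues
centred on it are concatenated into a 140-long vector (window positions
beyond a terminus contribute exact zeros). Features are standardized by
Z-score with statistics fitted **on the training fold only** — under
leave-one-protein-out cross-validation the held-out protein (and any
sequence with a pairwise E-value below 1e-4 to it) never influences the
normalization or the model. Hyperparameters are chosen by a grid search
maximizing the pooled Matthews correlation coefficient (MCC). The raw SVM
decision value, not the thresholded label, is carried forward as a feature
for contact prediction.

## Residue contacts

Every residue pair on *different* TM helices is a candidate contact.
Three geometric definitions are supported, applied to heavy atoms:

1. C-beta–C-beta distance at most 8 Å (C-alpha for glycine);
2. any atom pair closer than the sum of their van der Waals radii plus
   0.6 Å;
3. any backbone/side-chain heavy-atom pair closer than 5.5 Å.

Definition 1 uses a non-strict cutoff (a *maximal* distance of 8 Å);
definitions 2 and 3 are strict. Bondi-style element radii (C 1.70, N 1.55,
O 1.52, S 1.80, P 1.80 Å) are the default vdW table and are configurable.
A missing C-beta on a non-glycine residue falls back to the C-alpha with a
warning rather than silently dropping the pair.

The pair feature vector (292 values at defaults) concatenates the two
residues' 140-long profile windows (280), their two raw lipid-exposure SVM
scores, a one-hot sequence-separation encoding over the bins
≤50, 51–75, …, 176–200, >200 residues (8 bits, inclusive-left), and two
relative positions within the helices. The relative position is the
residue's 1-based position in its helix divided by the helix length
("relative Z"), and the second residue's value is complemented
(`1 - (pos - start)/length`) when the two helix indices differ by an odd
number — in a membrane, sequence-adjacent helices run antiparallel, so
the complement aligns the two values on a common depth axis. Both values
stay in (0, 1], and flipping twice is the identity.

Observed contact/non-contact labels are heavily imbalanced (about 1:50 on
real structures). Training sets are balanced by randomly undersampling
negatives to the positive count; any residual imbalance is absorbed by the
SVM cost factor `j = n_neg/n_pos`, so the effective ratio is exactly 1:1.

## Interactions, decoys, and the packing arrangement

Two helices interact when at least one residue pair between them is in
contact — the same rule is applied to observed contacts and to predicted
scores (score > 0). A candidate arrangement (native structure, homology
model, or decoy) is scored by counting, over all `choose(n, 2)` helix
pairs, how many agree in interaction status with the prediction;
interacting and non-interacting pairs score equally, and the native is
"ranked first" when no decoy scores strictly higher (ties count in the
native's favour; this tie rule is switchable).

The interaction graph is then embedded in the plane with a Kamada–Kawai
spring layout: vertices start on a regular n-gon (radius 1 layout unit),
the spring between vertices i and j has rest length `L0·d_ij` and strength
`K/d_ij²`, where `d_ij` is the graph-theoretic shortest-path distance, and
energy is minimized by per-vertex damped Newton sweeps with backtracking,
so the energy provably never increases; iteration stops when the largest
vertex gradient falls below 1e-6 (at most 1000 sweeps per vertex on
average). A disconnected graph is a hard error — an arrangement cannot be
generated when some helices have no predicted interactions at all. The
converged layout is rescaled so the minimum inter-helix distance is 10 Å,
a typical helix-axis packing distance.

When several helices share the same interactions (identical neighbour
sets after removing the candidate pair from each other's sets), their
assignments to layout slots are interchangeable; all within-class
permutations are enumerated (capped at 10,000, beyond which a seeded
sample is drawn). Each arrangement is scored by its number of *same-side
loop crossovers*: loop i joins the positions of helices i and i+1, loops
alternate membrane sides with parity, and two loops on the same side cross
when their open segments properly intersect (cross-product orientation
signs; shared endpoints and collinear touching do not count). Arrangements
are ranked by crossovers, then by total contact distance, then by id.

Finally, residues are placed on helical wheels (100°/residue — the
canonical 3.6-residues-per-turn alpha-helix twist — at radius 2.3 Å, an
approximate C-beta radial distance) and a genetic algorithm chooses one
integer rotation per helix in 0–359° minimizing the summed 2-D distance
over contact pairs. GA defaults: population 100, 200 generations,
tournament size 3, uniform per-gene crossover at rate 0.9, per-gene
mutation 0.05 (uniform redraw), elitism 1, fully seeded. With elitism the
best objective is non-increasing and the result never falls below the best
initial individual. The membrane-normal coordinate is ignored throughout:
the packing problem is treated as strictly 2-D. Azimuth increases
counter-clockwise viewed from the extracellular side; helices of either
orientation use the same twist sign by default (a per-helix sign flag
provides the mirror convention).

## The synthetic generator

Because the real training corpus (crystal structures, coarse-grained
simulation labels, large-database profiles, reconnection decoys) is not
shippable, `make_bundle()` generates idealized bundles at desk scale:
ideal helices (rise 1.5 Å/residue, twist 100°/residue) with pseudo-atoms
N, CA, C, O, CB plus one extended side-chain atom 2.5 Å from the C-beta,
axes on a ring with 9.5 Å spacing between ring-adjacent helices,
antiparallel alternation (odd helices up, even down), 16-residue helices
joined by 4-residue loops, and per-helix azimuth offsets drawn from the
seed. Ground-truth contacts are labelled by an independent brute-force
per-residue-pair scan, and the interaction graph follows from them. These
defaults were chosen once as a realistic idealization: ~9–10 Å is a
typical TM helix packing distance, 16–20 residues a typical TM helix
length, and the ring geometry reproduces the neighbour-only interaction
pattern of regular bundles.

`make_profiles()` plants a recoverable sequence signal with two
components, mimicking what evolution writes into TM helix profiles:
a binary hydrophobic/polar contrast (lipid-facing residues enriched in
hydrophobic columns and depleted in polar ones, and the reverse for the
core) and a *graded* interface-propensity component on the remaining
columns, proportional to how directly the side chain faces the bundle
core — the analogue of the small-residue/aromatic packing-motif
enrichment of real helix–helix interfaces. The lipid-contact fraction is
graded with the same geometry (`0.5 + 0.45·outwardness`), so the exposure
label coincides exactly with the side chain pointing away from the core.
Gaussian noise of standard deviation `1/signal_strength` is added to
every profile cell; the default `signal_strength = 4` (25% noise) is the
generator's "moderate signal" condition, `Inf` is the noiseless limit and
`0` removes the signal entirely (null calibration).

What passing on these fixtures shows — and what it does not: the
pipeline recovers a *planted, geometrically consistent* signal through
the full training protocol (fold-wise normalization, balancing, grid
search, pooled MCC), and all geometric operations agree with independent
oracles. It does not show that real profiles carry this much signal;
benchmarks on real structures sit far lower (per-pair MCC
around 0.28), because evolutionary signal is weaker and noisier than any
planted pattern.

## Evaluation protocols and problem sizes

- **Lipid recovery**: two-helix bundles; leave-one-protein-out CV with a
  small MCC-driven grid (gamma 0.003–0.03, C 1.5/10 — the near-linear RBF
  regime appropriate for 140 standardized features). Noiseless signal must
  give MCC 1.0 (4 proteins); zero signal stays within |MCC| < 0.15
  (30 proteins).
- **Contact recovery**: 20 two-helix proteins at the default signal.
  Training folds are balanced 1:1; held-out proteins are evaluated on
  class-balanced pair sets (all contacts plus an equal-size seeded
  subsample of non-contacts). The balanced evaluation makes the reported
  MCC a measure of signal recovery rather than of the generator's class
  ratio, which at two helices (~1:9) is far milder than the 1:50 of real
  structures and would otherwise dominate the statistic through the
  fixed score-0 threshold.
- **Decoy discrimination**: 50 bundles of 4–7 helices, 24 decoys each,
  predictions set to the observed graph — native-first must be 100% by
  construction.
- **Arrangement recovery**: 50 seven-helix rings with shuffled circular
  order; the top-ranked arrangement's cyclic order must match the
  generator's (up to rotation/reflection) in at least 95% of runs; a
  13-helix ring must complete end to end. Benchmarks use 10-residue
  helices, which leave contact sets and graphs unchanged while keeping
  the geometry checks fast.

## Numerical choices and edge cases

- Z-score uses the population standard deviation; constant columns map to
  exactly 0. Zero-padding at termini is applied before normalization, so
  padded cells transform to `-mean/sd` like any other value.
- The SVM decision-score sign is normalised after fitting so that positive
  scores always mean the positive class, independent of class ordering in
  the training data. The decision threshold is fixed at raw score 0; no
  top-L/5 re-thresholding is applied anywhere.
- Degenerate metric denominators (empty prediction or truth classes)
  yield 0 for the affected metric, and the report is flagged.
- Orientation tests for crossovers use the sign of the cross product;
  proper intersection requires strictly opposite orientations both ways,
  so touching endpoints and collinear overlap never count.
- The spring-layout minimizer falls back from the Newton step to the raw
  gradient whenever the local Hessian is not positive definite, and
  halves the step until the energy decreases.
- Coincident helix positions (zero-length loops) and disconnected
  interaction graphs are hard errors, not silent results.

## Worked example

```{r example}
set.seed(1)
spec <- bundle_spec(7, order = sample(7), seed = 42)
bundle <- make_bundle(spec)
bundle$graph

arr <- select_arrangement(bundle$graph, bundle$topo,
                          contacts = bundle$contacts,
                          ga = ga_config(pop_size = 40, generations = 60),
                          seed = 1)[[1]]
arr
# cyclic order of the layout vs the generator's ground truth
ang <- atan2(arr$positions[, 2] - mean(arr$positions[, 2]),
             arr$positions[, 1] - mean(arr$positions[, 1]))
order(ang)
spec$order
```

## Known limitations

- Re-entrant, strongly tilted and kinked helices are outside the model:
  every helix is treated as a vertical ideal helix.
- Consecutively connected topologies (e.g. interactions 1–2 and 2–3 only)
  are ambiguous for the layout: the spring system relaxes to a circular
  arrangement even when the true packing is linear.
- The synthetic generator plants its signal in profile *columns*; real
  evolutionary couplings (co-evolution between contacting positions) are
  deliberately not emulated, matching the finding that such scores added
  nothing once lipid-exposure scores were included.
- Helix-axis tilt, kinks, and inter-chain contacts in complexes are not
  modelled.
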