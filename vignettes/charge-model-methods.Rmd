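---
title: "Methods: graph-neural charge equilibration in qeqnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-neural charge equilibration in qeqnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its model, the choices made
where the design was genuinely open, and what the shipped experiments do and
do not demonstrate.

## The model and its assumptions

`qeqnet` assigns per-atom point charges in two stages.

**Perception.** A molecule is a graph: atoms are nodes, bonds are
(featureless, bidirectional) edges. Each atom starts from purely topological
descriptors and is refined by `K` rounds of message passing — an edge update
applied to every directed bond, an index-invariant (SUM or MEAN)
aggregation over incident edges, and a node update; both updates are
two-layer tanh networks. The scheme is permutation-equivariant by
construction, and after `K` rounds an atom's embedding depends only on its
radius-`K` neighborhood.

**Charging.** A linear readout head maps the final embedding of atom *i* to
an electronegativity `e_i` (energy/charge) and, through a softplus, a
strictly positive hardness `s_i` (energy/charge²). The charges minimize the
second-order charging energy `sum_i (e_i q_i + s_i q_i^2)` subject to
`sum q_i = Q`, the integer sum of formal charges. With `s_i > 0` this is a
strictly convex equality-constrained quadratic with the closed-form unique
solution `q_i = (lambda - e_i) / (2 s_i)`, where the multiplier `lambda` is
the uniform value of `e_i + 2 s_i q_i` at the optimum.

Three modeling assumptions are worth making explicit:

* *Geometry is irrelevant.* No conformers, no 3D coordinates, no
  bond-order-dependent features. Resonance-equivalent depictions of a
  molecule must give identical predictions.
* *Interatomic electrostatics are neglected in the charging energy.* That
  truncation is what makes the constrained minimum closed-form and O(N);
  all interaction effects must be absorbed by the learned `e_i`, `s_i`.
* *The quadratic uses the `s_i q_i^2` convention*, not `½ s_i q_i^2`.
  Hardness values from other charge-equilibration literature differ by a
  factor of two.

## Featurization and resonance independence

Per-atom features: element one-hot over the vocabulary
`{H, C, N, O, S, P, F, Cl, Br, I}`, total-degree one-hot (1–6; a monatomic
ion has an all-zero degree block), formal-charge one-hot (−2..+2),
ring-membership flag, aromaticity flag (23 features). The exact descriptor
set of published neural charge models is typically tuned; this set is a
documented stand-in, stamped with a version tag (`qeqnet-feat-1`) that
checkpoints record and the loader enforces.

A raw formal-charge feature would break resonance independence: in
acetate the charge is drawn on one oxygen, yet the two oxygens are
chemically indistinguishable. We therefore compute charge-blind
Weisfeiler–Lehman equivalence classes (initial colour = element, degree,
ring, aromatic; fixed 8 refinement sweeps, keeping the step O(N)) and
average the formal-charge one-hot within each class. Equivalent atoms then
have identical rows — and consequently identical embeddings and identical
charges — while atoms distinguishable by topology keep their own charge.
The cost is a rare over-merge: two sites that are topologically equivalent
but chemically distinct *only* through a localized charge more than eight
bonds from any distinguishing feature would share a fractional charge
feature. We consider this the right failure mode for a model whose claim is
resonance independence.

The same delocalized formal charge is used by the synthetic label generator
(below), so generated labels remain an exact function of the model's input
features — without this, topologically equivalent atoms would carry
different labels that no equivariant model could fit.

## Tunable parameters

| parameter | default | units / range | rationale |
|---|---|---|---|
| `n_layers` (K) | 3 | rounds | receptive field of radius 3 covers the functional groups the generator produces; published models tune this |
| `hidden`, `embed_dim` | 128 | – | comfortable over-parameterization; the desk-scale experiments use 64 |
| `agg` | SUM | SUM/MEAN | SUM preserves neighborhood size information; MEAN defined as zero over an empty neighborhood so monatomic ions work |
| hardness floor | 1e-6 | energy/charge² | strict convexity guard; the solver refuses anything at or below it |
| `lr` | 1e-3 (3e-3 in the recovery runs) | – | Adam on the summed squared loss |
| `epochs` / `patience` | 200 / 30 | – | early stopping on validation loss; best-validation snapshot returned |
| split fractions | 80/10/10 | by molecule | the standard train/validation/test layout for this task |
| bootstrap replicates | 1000 | – | percentile CI of the mean per-molecule RMSE |
| size-bin width | 10 atoms | – | stratified report granularity |

Training minimizes the *sum* over atoms of squared charge residuals, summed
over molecules — so large molecules weigh more. Whether published models
weight atoms or molecules equally is generally unstated; the sum is the
plainest reading of "squared loss" and is what `squared_loss()` computes.
Loss gradients flow analytically through the closed-form constrained
solution (the multiplier's dependence on every `e_j`, `s_j` included); the
backward pass is verified against numerical differentiation in the tests.

## The synthetic generator: what it emulates, what it does not

`generate_toy_molecules()` grows random trees over a small heavy-atom
alphabet with valence bookkeeping, places net charge on
protonatable/deprotonatable sites (N⁺, O⁻/S⁻), completes hydrogens, and
emits occasional monatomic halide ions and diatomics so the degenerate
sizes are exercised. `eem_reference_charges()` labels each molecule by
looking up per-element electronegativity/hardness in a shipped, hand-chosen
table (plausible ordering F > O > N > C ≈ H, all hardness positive; the
charge-adjustment slope is negative so a formally negative site becomes more
electronegative and draws negative partial charge, matching the model's
sign convention: raising `e_k` never raises `q_k`), then solves the same
constrained problem. Labels therefore satisfy the charge constraint by
construction and are exactly representable by the model family — which is
the point: the parameter-recovery experiment tests the *trainability of the
machinery*, not chemical accuracy.

What passing these experiments does **not** show: anything about real
AM1-BCC-style reference charges. Real labels are conformer-ensemble-derived,
only approximately topological, and chemically far more diverse (rings,
aromatic heterocycles, correlated substituent effects); the generator's
trees contain no rings at all, and its label function is exactly inside the
model class while real charge schemes are not. Results on the generator
bound the approximation error of the pipeline from below, never the
chemistry error from above.

`make_chain_graph()` builds acetyl-/N-methyl-capped polyalanine-like chains
(10 atoms per residue, 12 cap atoms) purely as a size series for the
scaling experiment; the atom identities are a fixture template, not
biochemistry.

## Numerical choices

* **Precision.** Everything runs in R doubles; the charging stage's
  conservation contract (`|sum q - Q| <= 1e-8`) and the KKT certificate
  (`e_i + 2 s_i q_i` constant to 1e-6) are asserted at that precision.
* **Initialization.** Fan-in-scaled Gaussian weights from a recorded seed;
  zero biases except the hardness bias, set to `softplus⁻¹(1)` so initial
  hardness is ≈1 and early training does not flirt with the convexity
  floor.
* **Tie-breaks.** Rounding repair in the writers adds the post-rounding
  residual to the largest-|q| atom (first such atom on ties), so written
  records sum to Q exactly at 6 decimals.
* **Degenerate inputs.** Monatomic species: no edges, aggregation returns
  zero, the constraint alone fixes `q = Q`. Empty molecules, non-positive
  hardness, non-finite intermediates, and length mismatches raise typed
  conditions (`qeqnet_*_error`) rather than propagating garbage.
* **Batching.** Graphs are concatenated block-diagonally; the multiplier is
  solved segment-wise, one per molecule. Batched and sequential results
  agree to ~1e-15 in practice; the tests assert 1e-6.
* **Minibatches.** The training partition is drawn once from the seeded
  shuffle and reused across epochs — removing one source of run-to-run
  variance and making two same-seed runs bit-identical.

## Other open decisions

* Edges carry no chemical features (bond order is partially
  resonance-dependent); messages are functions of endpoint embeddings only.
* Update networks use per-layer (unshared) weights; sharing is a plausible
  variant the container format could express but does not default to.
* Atom and edge indices are 1-based throughout, the R idiom; writers
  translate where formats require otherwise.
* OpenBabel silently repairs some malformed SMILES, so the parser runs a
  lexical screen (bracket/branch balance, ring-closure pairing) first and
  rejects such records with a typed parse error.
* Multi-fragment records are rejected: the total-charge constraint is only
  well-defined per connected molecule, and guessing a per-fragment split
  would be silent chemistry.
* The CLI is a thin wrapper over `charge_cli()`, so its behaviour (exit
  statuses, fail-fast semantics, atomic output) is unit-testable in R.

## Problem sizes used by the shipped experiments

The test-suite and acceptance-script experiments run at desk scale, chosen
once: 1000 random instances for the solver-versus-minimizer and KKT checks;
100-molecule batches for batching equivalence; 600 generated molecules
(80/10/10 split), K = 3, width 64, 150 epochs for parameter recovery;
chains of 10–160 residues (112–1612 atoms) for the scaling exponent. The
recovery threshold asserted is a held-out mean per-molecule RMSE of 0.01 e.

## Known limitations

* One-hot element encoding cannot generalize to elements absent from the
  vocabulary; out-of-vocabulary atoms are refused, not guessed.
* No interatomic electrostatics in the charging objective; conformational
  charge polarization is out of scope by design.
* The aromaticity flag reflects OpenBabel/ChemmineR perception; exotic
  delocalized systems may be perceived differently by other toolkits.
* Bond orders are not stored on internally generated molecules; their SDF
  output is connectivity-only (parsed molecules keep their normalized
  record, including bond orders).
* No trained weights are distributed; users train against their own
  reference charges or use the synthetic generator for methodology work.
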