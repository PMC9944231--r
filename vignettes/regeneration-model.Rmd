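---
title: "A three-level self-repair model of a planarian-like worm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-level self-repair model of a planarian-like worm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regenworm)
```

## The model organism

`regenworm` simulates a flat, planarian-like synthetic worm that restores
both its anatomy and its body-wide bioelectric state after arbitrary
damage.  The worm is a 2D cell lattice built from repeated 5×5 blocks of
somatic cells, each block anchored by a stem cell overlaid on the block's
centre cell.  The default body plan has a 6×18-block rectangular body
flanked by triangular head and tail tissues of 21 blocks each (column
heights 6, 5, 4, 3, 2, 1), for 150 blocks in total: 3750 somatic cells
and 150 stem cells (4% of the 3900 cells, a deliberately small stem
fraction that still suffices for every recovery case).  The triangles are
right triangles anchored to one lattice edge so that the convex hull of
each end tissue's block centres has exactly three vertices; this is what
makes the measured corner counts come out as 3/4/3 and the bounding-box
aspect ratios as 1/3/1 — the minimal body-plan descriptors (`d` = 18
block columns of body, `AR`, `n`) that the *information field* stores for
whole-tissue regrowth.

Every cell holds a normalized membrane voltage.  At homeostasis the worm
is hyperpolarized everywhere (all voltages strictly negative) with a
voltage magnitude that decreases monotonically from head to tail.  The
organism is partitioned into 13 nodes for global monitoring: 9 body nodes
of 12 blocks (12 stem + 300 somatic cells) and two slightly smaller nodes
at each end (11 + 10 blocks in the head, mirrored in the tail).  Voltage
is held constant within a node; the published per-node values are not
machine-readable, so the default gradient is linear from −0.95 (node 1)
to −0.35 (node 13), configurable through
`assign_bioelectric_pattern()` — no recovery contract depends on the
specific numbers, only on negativity and monotonicity, which are
validated.

Coordinates are 1-based `(row, col)` with row 1 the dorsal edge and
column 1 the anterior tip; gap-junction adjacency is the 4-neighbourhood.

## Three communication motifs

Cells detect missing neighbours with three trained perceptron *motifs*,
one per lattice position class: corner (2 inputs), border (3), interior
(4).  Inputs are binarised voltage presence — 1 for a live hyperpolarized
neighbour, 0 for a dead or missing one (`standardize_inputs()`) — and the
trained unit outputs 1 exactly when all neighbours are present, i.e. the
k-input AND.  The weights stand for normalized gap-junction conductances.

Training starts from seeded random weights and applies the error-driven
update per truth-table row,

\[ w_j \leftarrow w_j + e\,\delta\,x_j,\qquad b \leftarrow b + e\,\delta,
   \qquad e = t - y, \]

with a hard output threshold at 0.5, learning rate δ = 0.1, and an epoch
budget of 1000.  The update is gated by the input \(x_j\): a uniform
(ungated) shift of all weights preserves their pairwise differences, so a
sufficiently adverse random start could never reach AND, whereas the
gated perceptron rule provably converges for this linearly separable
target.  Weight symmetry is *not* enforced — random initialisation
generally breaks it — and only functional equivalence to AND is part of
the contract, verified exhaustively over all ≤ 2⁴ inputs in the tests.

A cell's position class is taken from its expected neighbour count in the
*original* outline, so outline cells are never flagged as damaged merely
for having fewer neighbours.  The two tip blocks of the stem lattice have
a single stem neighbour; their presence check degenerates to that one
input.

## Somatic and stem networks

A voltage change below 10% of the homeostatic value is normal physiology;
a fractional change of 10% or more, or any dead cell, is damage
(`detect_change()`; the threshold comparison carries a 10⁻⁹ slack so the
exact-10% boundary is decided stably).  Cell death releases electrolytes
that depolarize the live 4-neighbours; this is modelled as a 15% loss of
voltage magnitude (`border_depolarization`), a free parameter chosen
above the detection threshold since only a ">10%" bound is known.

Live cells whose motif reports a missing neighbour form the **somatic
damage border** (`find_somatic_border()`), which equals the set of live
cells 4-adjacent to a dead cell — an equivalence tested against a
brute-force oracle on randomized ablations.  The border and dead cells
alert the stem cells of the blocks they lie in (`propagate_to_stem()`).

Stem cells communicate through the straight line of somatic relay cells
between adjacent block centres.  A directional signal is lost when the
neighbour stem is dead or the *entire* relay line is dead (as across a
cut); a single dead relay cell does not sever it, since ion fluxes can
route around one missing cell — otherwise a lone somatic death would
masquerade as stem damage.  Affected stems apply the same motifs over
these signals; those reporting a loss form the **stem-cell border**.
Posterior→anterior stem interactions are inhibitory and all others
activating, mirroring the global network's sign structure; the signs are
bookkeeping for the communication flow and do not alter the binary
presence logic.

Damage is classified per connected dead component with three **pattern
primitives** — border stem cells to the left of the damage, above/below
it, and to its right.  Each primitive is read off the direction of the
disrupted communication: a border stem whose posterior signal is lost
sits to the damage's left, and so on.  (Evaluating the primitives against
the dead region's bounding box gives the same answer for rectangular
lesions but fails for L-shaped severed regions, where the box encloses
the surviving fragment itself.)  All three primitives ⇒ local damage,
enclosed if the region nowhere touches the outline, otherwise an open
border; exactly one ⇒ whole-tissue loss; two ⇒ large-scale open-border
damage.  A component that killed no stem cells is left to the somatic
network.  Components of differing classes are flagged composite and
repaired in order of severity.

After whole-tissue loss the border stems identify *what* is missing from
the direction of the silence: no anterior-side signal ⇒ everything
anterior is gone, no posterior-side signal ⇒ everything posterior, both ⇒
an isolated body fragment.  The missing tissues are then read off the
body plan's tissue spans.

## The associative memory network

The 13 nodes form a recurrent associative memory (a sparsified Hopfield
variant) whose units update asynchronously, in fixed order 1→13 for
reproducibility, as

\[ s_i = \theta\Big(\sum_j w_{ij}\,s_j + b_i\Big),\qquad
   \theta(a) = \min(1, \max(-1, a)), \]

with only anterior/posterior-adjacent nodes connected (24 directed links
plus 13 biases; full connectivity is available behind
`amn_config(full_connectivity = TRUE)` for comparison).  Weights are
initialised with the directional sign structure — head-to-tail links
non-negative (activation), tail-to-head non-positive (inhibition) — and
the signs are preserved by projection after every update.

Training presents perturbed copies of the homeostatic pattern
\(T\): half with every node shifted by up to ±10% (normal physiology),
half with 10–50% shifts and, in half of those, a contiguous run of nodes
zeroed (destroyed nodes read 0).  Each pattern drives the input-scaled
error rule \(w_{ij} \leftarrow w_{ij} + e_i\,\delta\,s_j\),
\(b_i \leftarrow b_i + e_i\,\delta\), \(e_i = T_i - s_i\), until the
largest error over an epoch falls below `tol` = 10⁻⁶ (defaults δ = 0.05,
500 patterns, 10⁴ epoch budget, seed 0).  Because the target is the
*same* fixed pattern under zero-mean input noise, the least-squares
solution drives the couplings towards zero and stores the pattern
essentially in the biases; the trained network is therefore strongly
contracting, recalls \(T\) from any within-regime perturbation in one or
two sweeps, and its recall basin is verified empirically over hundreds of
seeded perturbations rather than proven.  A restoration trajectory from
an unperturbed state has length 1, and the deviation from the attractor
is non-increasing along every within-regime trajectory.

The node state sensed by the network is the mean voltage of the node's
live somatic cells (0 for an empty node); after recall the nodal voltages
are pushed back down to every constituent cell, stems included.  A node
is only destroyed when *all* its cells die; after such a node is rebuilt,
`retrain_after_repair()` re-initialises exactly the links touching the
rebuilt nodes and retrains against the attractor fetched from the
information field — converged links elsewhere receive only
vanishing updates.

## The five-stage controller

`run_cycle()` implements the two operating modes: monitoring (1) →
change detection (2) → [no damage] restoration (5) → (1); or (2) →
damage identification (3) → repair (4) → restoration, with retraining if
nodes were destroyed (5) → (1).  Stage 4 dispatches by severity:

* **Local somatic repair** — for each dead cell the nearest live stem
  (Euclidean; ties anterior-most then dorsal-most — the biology says
  "any", determinism is chosen for testability) migrates, divides, and
  the new cell takes the producing stem's voltage; the stem returns home.
  Migration is instantaneous within a tick (no kinetics are specified).
* **Stem-region repair** — a deterministic border stem produces one new
  stem per missing block (same voltage as the producer); each new stem
  refills its block's dead somatic cells, guided by the somatic border,
  and regeneration stops exactly when the dead region is filled.
* **Whole-tissue regrowth** — border stems seed the missing tissues and
  growth adds one block column per direction per tick towards the target
  mask reconstructed from the information field, anterior- and
  posterior-missing tissues growing concurrently.  A new stem's voltage
  is the producer's scaled by the ratio of the two nodes' attractor
  voltages, so new cells sit lower on the gradient than their producers
  and converge after the final recall.

`cut_worm()` partitions the lattice by the cut planes themselves (each
plane-bounded rectangle holding live cells becomes a fragment) rather
than by live-cell connectivity, so a pre-existing enclosed lesion cannot
split off a spurious one-cell "fragment".  Planes snap naturally to block
boundaries; off-boundary cuts are allowed with a warning.
`run_until_homeostasis()` runs every fragment of a cut independently,
each regenerating into a complete worm, and terminates when the anatomy
equals the original mask cell-for-cell and every voltage matches its
attractor-implied value within 10⁻⁶.

```{r example}
worm <- build_worm()
worm$motifs <- train_motifs()
amn <- train_amn(worm)
res <- run_cycle(apply_scenario(worm, fixture_scenario("2a", worm)), amn)
stage_sequence(res$log)
table(res$regen$type)
```

## The damage cases

`fixture_scenario()` emits the seven documented cases.  1a kills one
interior somatic cell; 2a kills one stem cell plus its 24 surrounding
somatic cells (the centre somatic cell shares the stem's lattice position
and survives, which is what makes the regenerated count exactly
1 + 24); 2b applies the same lesion to all 12 blocks of one node; 3a cuts
the worm into head, body, and tail at the tissue boundaries; 3b combines
a tail amputation with an enclosed interior lesion; 4 applies a vertical
and a horizontal cut.  Cases 1b, 2b, 3b, and 4 are reconstructed
representatives of their damage classes — their precise geometries are
not published — with cell counts chosen to match the derivable ones
(e.g. 2b regenerates 12 stems + 288 somatic cells).  Because the 2b
lesion leaves the 12 centre cells alive, its node is never fully
destroyed and the retrain path is exercised by the cut cases instead.

## What the generator does and does not emulate

The synthetic worm exercises the *control logic* of regeneration:
detection thresholds, border identification, damage classification,
staged regrowth, and attractor recall, all at the study's scale (3900
cells, 13 nodes).  It does not emulate electrodiffusion physics, channel
noise, intra-node voltage heterogeneity (a config hook exists but the
model fixes voltage constant within a node), cell mechanics, migration
kinetics, 3D anatomy, or altered-morphology outcomes.  Passing tests
therefore certify the algorithmic contracts — not that real planarian
tissue behaves this way.

## Numerical choices and limitations

Determinism is enforced throughout: every stochastic step (weight
initialisation, training-pattern draws, perturbations) runs under an
isolated seeded RNG that does not disturb the caller's RNG state; repair
tie-breaks are fixed; the asynchronous sweep order is fixed.  Identical
configuration and seed give byte-identical stage logs.  Degenerate
inputs are rejected with named errors: non-negative or non-monotone
gradients, geometries violating the tissue invariants, perturbation of
dead cells, cut planes outside the lattice.  Known limitations: recall
is guaranteed only over the trained noise regimes; the published
supplementary weight values are not reproduced (functional contracts
replace them); and classification of damage shapes outside the three
primitives' reach (none arise in the supported scenarios) is surfaced as
an explicit error rather than guessed.

Problem sizes used in the shipped tests and the acceptance script — the
default 3900-cell worm, 500 training patterns, 200 recall perturbations,
100 random scenarios per oracle check — are the study's own scales and
run on one CPU in well under the stated per-case times.
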