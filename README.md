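# regenworm

A desk-scale simulator of a planarian-like synthetic worm that
autonomously restores **form** (its anatomy) and **function** (its
body-wide bioelectric pattern) after arbitrary damage — from a single
dead cell up to being cut into head, body, and tail, each piece
regenerating a complete worm.

It is aimed at researchers in computational regeneration, bioelectricity,
and self-repairing systems who want a small, fully deterministic,
testable implementation of stem-cell-mediated repair as a multi-level
neural control problem.

## The model

The worm is a 2D lattice of 3750 somatic cells in 150 five-by-five
blocks, each anchored by a stem cell (150 stem cells, 4% of the 3900
total): a 6×18-block body with triangular head and tail (21 blocks each),
giving tissue aspect ratios 1/3/1 and corner counts 3/4/3.  Every cell
holds a hyperpolarized membrane voltage whose magnitude decreases
monotonically head→tail.  Three levels cooperate:

1. **Somatic cell network** — every cell is a perceptron applying one of
   three trained *communication motifs* (corner k=2, border k=3,
   interior k=4) to the binarised presence of its neighbours' voltages
   (1 = live negative voltage, 0 = none).  Each motif is trained with the
   error-driven rule *w ← w + e·δ·x*, *b ← b + e·δ* to compute the
   k-input AND, so a 0 output pinpoints a missing neighbour; cells with
   missing neighbours form the damage border.
2. **Stem cell network** — an organism-wide perceptron network using the
   same motifs over signals relayed through intermediate somatic cells
   (posterior→anterior interactions inhibitory, others activating).
   Three *pattern primitives* — border stem cells to the left,
   above/below, and to the right of the damage — classify each lesion:
   all three ⇒ local (enclosed or open border), exactly one ⇒ whole
   tissue missing, with two directional rules then naming the missing
   tissues from the direction of the silenced communication.
3. **Associative memory network (AMN)** — 13 nodes (9 body nodes of 12
   blocks; 2 slightly different nodes at each end) form a sparsified
   Hopfield-style recurrent network, *s_i = θ(Σ_j w_ij s_j + b_i)* with
   θ the identity clamped to [−1, 1], head-to-tail links activating and
   tail-to-head inhibiting.  Trained on perturbed copies of the
   homeostatic pattern (±10% "normal" noise; 10–50% shifts and zeroed
   nodes for damage), it stores the 13-node voltage gradient as its
   attractor and recalls it by asynchronous sweeps after any
   perturbation or repair; after whole nodes are rebuilt it retrains the
   affected links from the information field.

A five-stage controller ties them together: monitoring → change
detection (±10% threshold) → damage identification → repair (stem
migration and division, guided by the damage border, or whole-tissue
regrowth from the information field's minimal body plan *d*, *AR*, *n*)
→ bioelectric restoration.

## Worked example

```r
library(regenworm)
worm <- build_worm()            # 3750 somatic + 150 stem cells, 13 nodes
worm$motifs <- train_motifs()   # the three AND motifs
amn <- train_amn(worm)          # store the gradient in the attractor
worm
#> <worm> 30x150 lattice, 3750 somatic + 150 stem cells, 13 AMN nodes

# cut the worm into head, body, and tail; every piece regrows the whole worm
res <- run_until_homeostasis(worm, amn, fixture_scenario("3a", worm))
res
#> <regen_result> 3 fragment(s)
#>  fragment 1: recovered = TRUE, stages 2->3->4->5->1, 3354 cells regenerated
#>  fragment 2: recovered = TRUE, stages 2->3->4->5->1, 1092 cells regenerated
#>  fragment 3: recovered = TRUE, stages 2->3->4->5->1, 3354 cells regenerated

worm_summary(res$fragments[[1]]$worm)
#> worm summary
#>   somatic cells : 3750 alive, 0 dead
#>   stem cells    : 150 alive, 0 dead (3.8% of total)
#>   AMN nodes     : 13 (mean 300 cells/node)
#>   tissue AR     : head 1.00, body 3.00, tail 1.00
#>   corners       : head 3, body 4, tail 3
#>   matches original anatomy: TRUE
```

The stage sequence `2→3→4→5→1` is the damage mode of the controller;
the head fragment regenerated 3354 cells (129 stem + 3225 somatic — the
129 blocks of the missing body and tail), and the terminal summary shows
full anatomical recovery with every voltage back on the stored gradient.
Seven documented damage cases ship as scenarios
(`fixture_scenario("1a")` … `"4"`): single-cell loss, scattered cells, a
stem cell with its 24 surrounding somatic cells, a whole-node lesion,
the triple cut, amputation plus interior lesion, and crossed cuts.

A thin command-line wrapper is installed as `exec/regenworm`
(subcommands `build`, `train`, `perturb`, `damage`, `run`, `fixtures`,
`report`) over the same functions; worm states serialize to a
schema-documented JSON (`inst/schema/`), scenarios to YAML.

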