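# gtcorrect

Gene-tree correction prior to duplication–loss reconciliation and
species-tree inference.

## What it does

Reconciling a gene tree *T* with a species tree *S* explains their
incongruence by gene duplications and losses, but the inferred history is
brittle: a few misplaced leaves in *T* can add spurious events wholesale.
Under the LCA mapping, every duplication vertex of *T* is either an
**apparent duplication** (AD — its child genome sets share a species, so
it is a duplication under *any* species tree) or a **non-apparent
duplication** (NAD — disjoint child genome sets). Each NAD exhibits a
species triplet split one way by *T* and another way by *S*: a
contradiction that duplicated copies cannot explain, and a signature of
misplaced leaves. A tree whose duplications are all apparent is
**MD-consistent** with *S*.

`gtcorrect` removes a minimum number of leaves or species so that no NAD
remains:

* **Known species tree** — `correct_tree()` collapses each maximal
  NAD-free AD subtree into a weighted leaf (copies become weights), solves
  a weighted maximum agreement subtree (WMAST) against *S* on every
  AD-free region, and restricts the tree to the surviving species,
  repeating until MD-consistent. The removal count *N* is provably minimal
  when *T* is uniquely leaf-labelled (the problem reduces to MAST:
  *N* = |*T*| − mast score) or when no AD vertex is an ancestor of a NAD
  vertex ("Constraint C"); otherwise it is a near-optimal heuristic, and
  `exact_min_removals()` provides the exhaustive optimum for comparison.
* **Unknown species tree** — `minimum_species_removal_inference()` groups
  the non-AD vertices of a forest into levels, builds per-level
  hypergraphs whose hyperedges are child genome sets, and removes minimum
  vertex cuts (max-flow on the clique expansion) until every level is
  disconnected; `infer_md_species_tree()` certifies the result by
  reconstructing a species tree with d(T<sub>i</sub>, S*) equal to each
  tree's AD count. `minsrr_via_minsri()` handles a known *S* by adding it
  to the forest.
* **Reconciliation toolkit** — `lca_map()`, `classify_events()`,
  `build_reconciliation()` (a DS-consistent extension with explicit loss
  subtrees), duplication/loss/mutation costs, `wrong_triplet()`.
* **Simulation studies** — seeded generators for random species trees,
  gene trees, MD-consistent trees and leaf-misplacement perturbations,
  plus runners comparing the heuristic with the exhaustive optimum and
  measuring misplaced-leaf detection.

Trees are rooted, binary, Newick-encoded (one per line for forests); gene
trees may repeat leaf labels. Leaf weights travel in the branch-length
slot (`(1:2,2:1);` = leaf 1 with weight 2).

## Worked example

The species tree is `((1,2),3)`. Starting from the loss-free gene tree
`(1,2)`, inserting a leaf labelled 3 as sibling of leaf 1 gives
`((1,3),2)` — one of the two placements that create a NAD:

```r
library(gtcorrect)
s <- parse_newick("((1,2),3);")
t <- parse_newick("((1,3),2);")
classify_events(t, s)
#>   node uid mapping      event
#> 1    4   4       4        NAD
#> 2    5   5       4 SPECIATION
#> d(T,S) = 1  (AD 0, NAD 1)
wrong_triplet(t, s, 4)$gene_split
#> $pair
#> [1] "1" "3"
#> $apart
#> [1] "2"
```

The gene tree groups species 1 with 3; the species tree groups 1 with 2.
Reconciling without correction charges 1 duplication and 3 losses
(mutation cost 4) for what was a single misplaced leaf:

```r
build_reconciliation(t, s)
#> reconciliation: 1 duplications, 3 losses (mutation cost 4)
#>   (((1,LOSS_2),3),((LOSS_1,2),LOSS_3));
correct_tree(t, s)
#> correction: 1 leaf removal(s) in 1 pass(es)
#>   removed: 3(uid 2)
#>   corrected: (1,2);
```

Correction removes exactly the inserted leaf (reported by its stable node
id, since labels can repeat), and the corrected tree reconciles with zero
duplications and zero losses.

A command-line front end covering classification, reconciliation,
agreement subtrees, correction, species-removal inference and the
simulation studies is installed under `exec/`:

```sh
gtcorrect correct -g gene.nwk -s species.nwk --report removed.tsv
gtcorrect minsri -f forest.nwk --species-tree inferred.nwk
```

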