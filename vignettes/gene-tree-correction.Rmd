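---
title: "Correcting gene trees with non-apparent duplications"
author: "gtcorrect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting gene trees with non-apparent duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtcorrect)
```

## The problem

Reconciliation embeds a gene tree $T$ into a species tree $S$ and reads the
incongruence between the two as duplications and losses. Its well-known
weakness is fragility: a handful of misplaced leaves in $T$ — a common
artefact of gene-tree estimation — can inflate the inferred history with
spurious duplications and losses. `gtcorrect` implements a preprocessing
strategy: identify the vertices of $T$ whose disagreement with $S$ *cannot*
be explained by the presence of multiple gene copies, treat them as
signatures of misplaced leaves, and delete a minimum number of leaves (or
species) so that no such vertex remains. The cleaned tree or forest can then
be reconciled, or used for species-tree inference, with far less distortion.

The package is aimed at users who already have rooted binary gene trees
(leaves labelled by species, labels repeating freely) and either a rooted
binary species tree or a forest of gene families from which a species tree
is to be inferred.

## Events under the LCA mapping

The LCA mapping $M$ sends every vertex $t$ of $T$ to the lowest common
ancestor in $S$ of the species below $t$. A vertex is a **duplication** iff
it maps to the same species vertex as one of its children; $d(T,S)$ counts
them, and the LCA mapping minimizes the duplication, loss and mutation
(duplication + loss) costs over all reconciliations.

Duplications split into two classes:

* **AD** (apparent duplication): the child genome sets intersect — some
  species holds gene copies on both sides. Such a vertex is a duplication
  under *every* species tree; it is intrinsic to the gene family.
* **NAD** (non-apparent duplication): the child genome sets are disjoint.
  The duplication verdict here comes entirely from the species tree, and
  every NAD vertex exhibits a species triplet $\{a,b,c\}$ split one way by
  the gene tree and another way by $S$ (`wrong_triplet()`). That is a
  phylogenetic contradiction that duplicated copies cannot explain, and
  the working hypothesis is that it flags misplaced leaves.

A tree whose duplications are all AD is **MD-consistent** with $S$; a
forest of such trees is an MD-forest.

```{r}
s <- parse_newick("((1,2),3);")
t <- parse_newick("((1,3),2);")
classify_events(t, s)
wrong_triplet(t, s, 4)
```

The cost of ignoring the single NAD above is steep: the tree, one random
leaf-insertion away from the loss-free `((1,2),3);`, already needs 1
duplication and 3 losses:

```{r}
build_reconciliation(t, s)
```

## Correction with a known species tree

`correct_tree()` removes a set of leaves so that the result is
MD-consistent with $S$, aiming at the minimum count $N$. The engine is a
reduction to agreement subtrees:

1. **Collapse** every maximal subtree that is rooted at an AD vertex and
   contains no NAD (the *AD-border*) into a single **weighted leaf**: the
   collapsed region is replaced by the species-tree shape on its species,
   each leaf weighted by its number of gene copies
   (`induced_weighted_tree()`, `build_ti()`). Duplications inside these
   regions are legitimate; only their species content matters upstream.
2. **Solve** a weighted maximum agreement subtree (`wmast()`) between each
   AD-free subtree of the collapsed tree (the *NAD-border* subtrees) and
   $S$. Dropping a weighted leaf stands for deleting all copies of that
   species in the region, so the removal count is the weight lost,
   $v(T^I_x) - v(W^{MAX}_x)$.
3. **Restrict** the gene tree to the surviving species of each subtree and
   repeat until no NAD remains.

Two classes admit an exactness guarantee. If $T$ is uniquely leaf-labelled
there are no ADs at all and the whole problem *is* MAST:
$N = |T| - \mathrm{mast}(T,S)$. If $T$ satisfies **Constraint C** — no AD
vertex is a proper ancestor of a NAD vertex — the collapse produces a
uniquely leaf-labelled weighted tree and one WMAST solves the problem
optimally; moreover every optimal solution then removes all copies of a
species or none. Outside these classes the algorithm is a heuristic with
$N \ge N_{opt}$, and the package ships the exhaustive oracle
(`exact_min_removals()`, ascending subset search bounded by the heuristic's
own $N$) to measure the gap.

```{r}
correct_tree(parse_newick("(((1,3),2),1);"), s)
exact_min_removals(parse_newick("(((1,3),2),1);"), s)$n_opt
```

`min_species_removal_correct()` answers the species-removal variant for
Constraint-C trees by running the *unweighted* MAST on the collapsed tree:
weights count copies, and copies are irrelevant when a whole species is
kept or dropped.

### WMAST and its independent oracle

The weighted agreement subtree is computed by the classical quadratic
dynamic program over subtree pairs, with the leaf base case scoring the
leaf's weight. The caterpillar expansion — replace a weight-$c$ leaf by a
caterpillar of $c$ unit leaves in both trees, solve plain MAST, collapse
back — is implemented separately (`wmast_by_expansion()`) and kept purely
as a cross-check; the equivalence of the two routes is asserted on seeded
random instances in the test suite, and the expansion path additionally
asserts that an optimal MAST keeps each caterpillar entirely or not at all.

## Correction with an unknown species tree

When no species tree is trusted, the package removes species rather than
leaves. Group the non-AD vertices of the forest into **levels** — level 0
holds the highest non-AD vertices, level $j$ their closest non-AD
descendants, with AD vertices passed through silently
(`compute_levels()`). For the forest to be an MD-forest, each level must be
realizable as one round of speciations, which holds iff the level's
**hypergraph** — vertices: species; hyperedges: the child genome sets of
the level's vertices — is disconnected. A connected level hypergraph
forces the removal of a **minimum vertex cut** (`min_vertex_cut()`,
computed on the clique expansion by vertex-split maximum flow over all
non-adjacent pairs). `minimum_species_removal_inference()` walks the
levels, cuts where needed, restricts the forest and continues; the result
is certified by `infer_md_species_tree()`, which reconstructs a species
tree by recursive connected-component decomposition and verifies
$d(T_i, S^*) = $ (number of AD vertices of $T_i$) for every tree.

The known-species-tree variant (`minsrr_via_minsri()`) simply adds $S$ to
the forest as one more gene tree: any certified species tree for the
enlarged forest must restrict $S$.

```{r}
f <- list(parse_newick("((1,2),3);"), parse_newick("((1,3),2);"))
minimum_species_removal_inference(f)$kept_species
```

## Simulation studies

Two seeded studies quantify the heuristic; they are re-runnable in full
via `run_optimality_experiment()` and `run_detection_experiment()` and
from `scripts/acceptance.R`.

**Random-tree model.** No standard model is canonical for this setting, so
the package fixes one and records it in every result object: topologies
grow by sequential uniform random-edge insertion (each new leaf grafted
onto a uniformly chosen edge, including the root edge), species-tree
labels are a random permutation, gene-tree labels are drawn uniformly
*with replacement* from the genome set. MD-consistent trees are generated
from $S$ by random leaf duplications (a uniform leaf becomes a cherry of
two copies), which provably preserves MD-consistency at every step.
Misplaced leaves are emulated by grafting uniform-label leaves at uniform
edges.

**Optimality.** Genome set of 5 species, tree sizes 6–14 in steps of 2,
100 random trees per size, keeping only trees with an AD vertex *above* a
NAD vertex (elsewhere the algorithm is provably exact). The study
compares $N$ against the exhaustive $N_{opt}$: at these conditions the
heuristic is exact on roughly 70% of retained trees and the per-size mean
error rate $(N - N_{opt})/N$ stays around 0.09–0.15. The sizes were chosen
so the exhaustive oracle (exponential in $N$) remains comfortable; the
whole study takes well under a minute.

**Detection.** Genome set of 10 species, MD-consistent trees of sizes
10–100 in steps of 10, perturbed by $s/10$ random insertions, 20 trials
per size. The detection percentage $(N/\mathit{NbAdded}) \times 100$ is
averaged excluding perturbed trees that remain MD-consistent (those
insertions are invisible to any NAD-based method by construction; the
inclusive average is also reported, with such trials contributing zeros).
Under this package's generator about two thirds of inserted leaves are
detected; the fraction is sensitive to the random-tree model, since it is
governed by how often a uniform insertion creates a resolvable NAD rather
than an AD.

**What the simulations do not emulate:** sequence-level estimation error
(misplacements here are single-leaf grafts, not NNI-style distortions or
long-branch artefacts), gene loss in the generated families
(MD trees are built by duplication only), biased duplication rates across
lineages, and incomplete taxon sampling. Passing these studies shows the
algorithmic claims — exactness classes, certificate validity, near-optimal
heuristic behaviour — not that real gene families carry NADs at any
particular rate.

## Numerical and design choices

* **Determinism.** All generators take a seed; every tie in the package is
  broken deterministically. Canonical Newick output orders children by
  smallest descendant label. Agreement ties are resolved per DP cell
  towards the lexicographically smaller kept label set (this reproduces,
  e.g., keeping {1,2} rather than the equally-scoring {1,3} on the
  three-species example); the contract is determinism of the witness, not
  global lexicographic minimality over all optima — the score is what the
  correction count depends on.
* **Iterated collapse.** When an AD vertex sits above a NAD, collapsing
  the AD-border can itself create a new ONLY-AD subtree (two collapsed
  regions sharing a species). `build_ti()` repeats the collapse until no
  such subtree remains; this guarantees that whenever a NAD exists, some
  AD-free border subtree contains one, so every correction pass removes at
  least one leaf and the recursion terminates. Under Constraint C a single
  collapse suffices and the construction coincides with the textbook
  $T^I$.
* **Hypergraph vertex set.** A level hypergraph is built over the species
  actually covered by its hyperedges, not the full genome set — species
  absent from a level would otherwise disconnect it vacuously and the cut
  condition would never fire.
* **Fallbacks in inference.** A complete clique expansion has no vertex
  cut; the species with fewest gene copies is removed instead (ties:
  smallest label). Likewise, if a full walk over the levels makes no cut
  but the final certificate fails (levels are a global notion, the
  certificate a recursive one, so this is possible), one such species is
  removed before re-running — the genome set strictly shrinks, and any
  two-species forest certifies, so termination is unconditional.
* **Degenerate inputs.** Single-leaf trees are representable (restriction
  may produce them) but forests drop trees with fewer than two leaves
  before analysis — a two-leaf tree is MD-consistent with every species
  tree and constrains nothing. Multifurcations are rejected outright: the
  model is strictly binary.
* **Leaf identity.** Gene copies share labels, so removed leaves are
  reported by stable node identifiers (`uid`) that survive restriction,
  alongside their species labels.
* **Loss accounting.** Losses are the grafted subtrees of the LCA
  reconciliation, charged per gene-tree edge as the number of species
  vertices strictly between the endpoint mappings, plus one at a
  duplication parent; nothing is charged above the gene-tree root. Graft
  roots serialize with a `LOSS_` label prefix (an underscore, not a colon,
  keeps the output valid Newick).

## Limitations

NAD vertices flag only a subset of misplaced leaves — an insertion that
lands compatibly, or inside an AD region, is undetectable by construction.
Conversely a NAD identifies a wrong *triplet*, not a unique culprit leaf:
the optimal removal set is generally not unique, and the package returns
one deterministic witness rather than enumerating all optima. The
species-removal inference is a greedy heuristic over levels; only the
certificate, not minimality, is guaranteed. Genome sets are manipulated as
bitmask words, and the agreement dynamic program stores witness sets per
subtree pair; both are sized for gene families up to a few hundred leaves,
the regime the correction problem targets.
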