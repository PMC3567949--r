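Package: gtcorrect
Title: Gene Tree Correction for Reconciliation and Species Tree Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Preprocessing of gene trees prior to duplication-loss
    reconciliation or species-tree inference. Flags non-apparent duplication
    (NAD) vertices of a gene tree against a species tree as signatures of
    misplaced leaves, and removes a minimum number of leaves (via a
    weighted maximum agreement subtree algorithm) or species (via minimum
    vertex cuts in level hypergraphs) so that the gene tree or forest
    becomes consistent with a species tree using apparent duplications
    only. Includes LCA-mapping reconciliation with duplication, loss and
    mutation costs, exhaustive optimality oracles, and seeded simulation
    studies of the correction heuristic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
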