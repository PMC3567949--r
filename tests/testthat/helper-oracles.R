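# Independent brute-force oracles and small generators used across the
# suite. Oracles enumerate exhaustively and never call the code path they
# check.

nwk <- function(text) parse_newick(text)

iso <- function(a, b) identical(write_newick(a), write_newick(b))

# every rooted binary topology on a label set, by recursive insertion of
# the next label onto every edge (including the root edge)
all_species_trees <- function(labels) {
  if (length(labels) == 1) return(list(leaf_tree(labels)))
  if (length(labels) == 2)
    return(list(join_trees(leaf_tree(labels[1]), leaf_tree(labels[2]))))
  out <- list()
  for (t in all_species_trees(labels[-length(labels)])) {
    for (at in seq_len(t$n)) {
      g <- graft_on_edge(t, at, leaf_tree(labels[length(labels)]))
      g$graft <- NULL
      out[[length(out) + 1L]] <- g
    }
  }
  out
}

# exhaustive maximum agreement over label subsets; tie: lexicographically
# smallest sorted subset (matching the package's determinism contract is
# not required -- only the score is compared where ties exist)
brute_agreement <- function(t, s, wt) {
  labs <- sort(genome_set(t))
  best_score <- -1; best_set <- NULL
  for (k in rev(seq_along(labs))) {
    for (K in utils::combn(labs, k, simplify = FALSE)) {
      rt <- restrict_to(t, K); rs <- restrict_to(s, K)
      if (is.null(rt) || is.null(rs)) next
      rt$weighted <- FALSE; rs$weighted <- FALSE
      rt$weight[] <- ifelse(is.na(rt$kids[, 1]), 1, NA)
      rs$weight[] <- ifelse(is.na(rs$kids[, 1]), 1, NA)
      if (iso(rt, rs)) {
        sc <- sum(wt[K])
        if (sc > best_score) { best_score <- sc; best_set <- K }
      }
    }
  }
  if (is.null(best_set)) list(score = 0, kept = character(0))
  else list(score = best_score, kept = best_set)
}

brute_mast_score <- function(t, s) {
  labs <- genome_set(t)
  brute_agreement(t, s, structure(rep(1, length(labs)), names = labs))$score
}

brute_wmast_score <- function(w, s) {
  lv <- which(is.na(w$kids[, 1]))
  brute_agreement(w, s, structure(w$weight[lv], names = w$label[lv]))$score
}

# exhaustive minimum vertex cut of a level hypergraph: smallest vertex
# subset whose deletion (from V and every hyperedge) disconnects it
brute_min_cut <- function(h) {
  disconnects <- function(rm) {
    V <- setdiff(h$vertices, rm)
    if (length(V) < 2) return(FALSE)
    memb <- structure(seq_along(V), names = V)
    for (e in h$edges) {
      e <- setdiff(e, rm)
      ids <- unique(memb[e])
      if (length(ids) > 1) memb[memb %in% ids] <- ids[1]
    }
    length(unique(memb)) > 1
  }
  for (k in 0:(length(h$vertices) - 2)) {
    for (rm in utils::combn(h$vertices, k, simplify = FALSE)) {
      if (disconnects(rm)) return(rm)
    }
  }
  NULL
}

random_hypergraph <- function(nv, ne) {
  V <- as.character(seq_len(nv))
  edges <- lapply(seq_len(ne), function(i)
    sample(V, sample(1:max(2, nv %/% 2), 1)))
  structure(list(vertices = sort(unique(unlist(edges))), edges = edges),
            class = "level_hypergraph")
}

# uniquely leaf-labelled random gene tree (labels sampled without
# replacement)
random_unique_tree <- function(size, species) {
  labs <- sample(species, size)
  t <- join_trees(leaf_tree(labs[1]), leaf_tree(labs[2]))
  for (lab in labs[-(1:2)]) {
    t <- graft_on_edge(t, sample.int(t$n, 1), leaf_tree(lab))
    t$graft <- NULL
  }
  t$uid <- seq_len(t$n)
  t
}
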