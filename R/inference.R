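## Species-tree side: level sets of non-AD vertices, per-level hypergraphs
## over the species, minimum vertex cuts in their clique expansions, and
## the greedy species-removal heuristic with an MD-forest certificate.

restrict_forest <- function(forest, keep) {
  f <- lapply(forest, restrict_to, keep = keep)
  f[!vapply(f, is.null, TRUE) & vapply(f, function(t)
    if (is.null(t)) 0L else tree_size(t), 0L) > 1]
}

#' Level sets of a gene-tree forest
#'
#' Level 0 holds the highest vertices of each tree that are not apparent
#' duplications (AD-ness here is species-tree-free: intersecting child
#' genome sets); level j holds their closest non-AD internal descendants,
#' the recursion passing through AD vertices without incrementing the
#' level. Leaves carry no bipartition and never enter a level. For a
#' forest to be an MD-forest, every level's vertices must be realizable
#' as speciations under a single species tree.
#'
#' @param forest list of `gtree`.
#' @return object of class `level_sets`: `$levels`, a list (one entry per
#'   level) of data frames with columns `tree` and `node`.
#' @export
compute_levels <- function(forest) {
  rows <- list()
  for (i in seq_along(forest)) {
    t <- forest[[i]]
    af <- ad_flags(t)
    rec <- function(v, j) {
      if (is_leaf(t, v)) return(invisible())
      if (!af$ad[v]) {
        rows[[length(rows) + 1L]] <<- c(i, v, j)
        rec(t$kids[v, 1], j + 1L); rec(t$kids[v, 2], j + 1L)
      } else {
        rec(t$kids[v, 1], j); rec(t$kids[v, 2], j)
      }
    }
    rec(t$root, 0L)
  }
  if (!length(rows))
    return(structure(list(levels = list()), class = "level_sets"))
  m <- do.call(rbind, rows)
  levels <- lapply(sort(unique(m[, 3])), function(j) {
    data.frame(tree = m[m[, 3] == j, 1], node = m[m[, 3] == j, 2])
  })
  structure(list(levels = levels), class = "level_sets")
}

#' @export
print.level_sets <- function(x, ...) {
  cat(sprintf("level sets: %d level(s), sizes %s\n", length(x$levels),
              paste(vapply(x$levels, nrow, 0L), collapse = ", ")))
  invisible(x)
}

#' Hypergraph of a level's bipartitions
#'
#' Each level-j vertex x contributes its two child genome sets as
#' hyperedges. The vertex set is the species covered by those hyperedges
#' (species absent from the level would otherwise make the hypergraph
#' trivially disconnected and the cut condition vacuous).
#'
#' @param level one element of `compute_levels(forest)$levels`.
#' @param forest the forest the level was computed from.
#' @return object of class `level_hypergraph`: `$vertices` (species) and
#'   `$edges` (list of species sets).
#' @export
build_level_hypergraph <- function(level, forest) {
  edges <- list()
  for (k in seq_len(nrow(level))) {
    t <- forest[[level$tree[k]]]
    x <- level$node[k]
    edges <- c(edges, list(genome_set(t, t$kids[x, 1])),
               list(genome_set(t, t$kids[x, 2])))
  }
  structure(list(vertices = sort(unique(unlist(edges))), edges = edges),
            class = "level_hypergraph")
}

#' @export
print.level_hypergraph <- function(x, ...) {
  cat(sprintf("level hypergraph: %d species, %d hyperedges\n",
              length(x$vertices), length(x$edges)))
  invisible(x)
}

clique_expansion <- function(h) {
  adj <- matrix(FALSE, length(h$vertices), length(h$vertices),
                dimnames = list(h$vertices, h$vertices))
  for (e in h$edges) {
    if (length(e) > 1) adj[e, e] <- TRUE
  }
  diag(adj) <- FALSE
  adj
}

#' Connectivity of a level hypergraph
#'
#' True iff the clique expansion (every hyperedge replaced by a clique on
#' its members) is connected over the hypergraph's vertex set. A
#' connected level hypergraph means no species tree can make all of that
#' level's vertices speciations.
#'
#' @param h a `level_hypergraph`.
#' @export
hypergraph_connected <- function(h) {
  if (!length(h$vertices)) stop("empty hypergraph")
  g <- igraph::graph_from_adjacency_matrix(clique_expansion(h),
                                           mode = "undirected")
  igraph::components(g)$no == 1
}

#' Minimum vertex cut of a level hypergraph
#'
#' A minimum-cardinality species set whose removal (from the vertex set
#' and from every hyperedge) disconnects the hypergraph. A set of
#' vertices disconnects the hypergraph iff it disconnects the clique
#' expansion, so the cut is computed on the simple graph by s-t
#' vertex-capacity maximum flow (vertex splitting) over all non-adjacent
#' pairs. Returns `NULL` when the expansion is a complete graph (no cut
#' can disconnect it).
#'
#' @param h a connected `level_hypergraph`.
#' @return character vector of removed species, or `NULL`.
#' @export
min_vertex_cut <- function(h) {
  adj <- clique_expansion(h)
  V <- h$vertices
  nv <- length(V)
  pairs <- which(!adj & upper.tri(adj), arr.ind = TRUE)
  if (!nrow(pairs)) return(NULL)      # complete expansion: no cut exists
  big <- nv + 1
  ## split graph: vertex i -> nodes i (in) and nv+i (out)
  ghalf <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- rbind(cbind(nv + ghalf[, 1], ghalf[, 2]),
                 cbind(nv + ghalf[, 2], ghalf[, 1]),
                 cbind(seq_len(nv), nv + seq_len(nv)))
  caps0 <- c(rep(big, 2 * nrow(ghalf)), rep(1, nv))
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  best <- NULL
  for (k in seq_len(nrow(pairs))) {
    s <- pairs[k, 1]; t <- pairs[k, 2]
    caps <- caps0
    caps[2 * nrow(ghalf) + c(s, t)] <- big
    fl <- igraph::max_flow(g, source = nv + s, target = t, capacity = caps)
    ## a min cut of value < big consists of splitting edges i -> nv+i only
    cutv <- sort(V[as.integer(igraph::ends(g, fl$cut)[, 1])])
    if (is.null(best) || length(cutv) < length(best) ||
        (length(cutv) == length(best) && set_less(cutv, best)))
      best <- cutv
  }
  best
}

## species with fewest leaf occurrences across the forest (tie: smallest
## label) -- progress fallback when no vertex cut exists
fewest_occurrences_species <- function(forest, among) {
  occ <- structure(numeric(length(among)), names = among)
  for (t in forest) {
    lv <- leaf_nodes(t)
    cnt <- table(t$label[lv][t$label[lv] %in% among])
    occ[names(cnt)] <- occ[names(cnt)] + cnt
  }
  names(occ)[order(occ, names(occ))][1]
}

#' Greedy minimum species removal for species-tree inference
#'
#' Walks the level sets of the forest; whenever a level's hypergraph is
#' connected, removes a minimum vertex cut from the genome set and
#' restricts the forest, then continues with the next level. The result
#' is certified by [infer_md_species_tree()] on the restricted forest;
#' if certification fails (earlier levels may have changed after a
#' restriction) the walk is re-run on the current genome set until it
#' certifies. When a level's clique expansion is complete (no cut
#' exists), the species with fewest gene copies is removed instead, so
#' the genome set strictly shrinks and the algorithm terminates -- a
#' two-species forest is always an MD-forest.
#'
#' @param forest list of `gtree`.
#' @return list with `$kept_species` (G'), `$removed_species`,
#'   `$species_tree` (certified parsimonious species tree of the
#'   restricted forest) and `$forest` (the restriction).
#' @export
minimum_species_removal_inference <- function(forest) {
  G <- forest_genome_set(forest)
  Gp <- G
  repeat {
    before <- length(Gp)
    f <- restrict_forest(forest, Gp)
    j <- 0L
    repeat {
      lv <- compute_levels(f)$levels
      if (j + 1L > length(lv)) break
      h <- build_level_hypergraph(lv[[j + 1L]], f)
      if (length(h$vertices) > 1 && hypergraph_connected(h)) {
        cut <- min_vertex_cut(h)
        if (is.null(cut)) cut <- fewest_occurrences_species(f, h$vertices)
        Gp <- setdiff(Gp, cut)
        f <- restrict_forest(f, Gp)
      }
      j <- j + 1L
    }
    fin <- restrict_forest(forest, Gp)
    st <- infer_md_species_tree(fin, genome_set_hint = Gp)
    if (!is.null(st)) {
      return(list(kept_species = Gp, removed_species = setdiff(G, Gp),
                  species_tree = st, forest = fin))
    }
    ## certificate failed with no cut performed: force progress so |G'|
    ## strictly decreases (a two-species forest always certifies)
    if (length(Gp) == before)
      Gp <- setdiff(Gp, fewest_occurrences_species(fin, Gp))
  }
}

#' Species removal against a known species tree, via inference
#'
#' Adds the species tree to the forest as one more (uniquely
#' leaf-labelled) gene tree and runs
#' [minimum_species_removal_inference()]: any species tree certified for
#' the enlarged forest must restrict `s`, so the kept species make the
#' forest MD-consistent with the corresponding restriction of `s`.
#'
#' @param forest list of `gtree` with labels drawn from `s`.
#' @param s species tree.
#' @return list with `$kept_species`, `$removed_species`, `$forest` (the
#'   restricted forest) and `$species_tree` (restriction of `s`).
#' @export
minsrr_via_minsri <- function(forest, s) {
  check_species_tree(s)
  res <- minimum_species_removal_inference(c(forest, list(s)))
  kept <- res$kept_species
  srs <- restrict_to(s, kept)
  fin <- restrict_forest(forest, kept)
  for (t in fin) {
    if (!is_md_consistent(t, srs))
      stop("internal error: restricted forest not MD-consistent")
  }
  list(kept_species = kept,
       removed_species = res$removed_species,
       forest = fin, species_tree = srs)
}

#' Decide the MD-forest property and build a parsimonious species tree
#'
#' Recursive component construction: on a species set, build the level-0
#' hypergraph of the restricted forest; if its clique expansion has at
#' least two connected components (species covered by no bipartition are
#' isolated), recurse into each component and join the resulting subtrees
#' with a left-deep caterpillar over components ordered by smallest
#' species label; if it is connected over more than one species, no
#' species tree exists and the result is `NULL`. A non-`NULL` tree S* is
#' certified before returning: d(T, S*) must equal the AD-vertex count of
#' every tree (so every duplication is apparent).
#'
#' @param forest list of `gtree`.
#' @param genome_set_hint species set to build over (defaults to the
#'   forest's genome set; species in the hint but absent from the forest
#'   are unconstrained and join as isolated components).
#' @return a species tree (`gtree`) or `NULL`.
#' @export
infer_md_species_tree <- function(forest, genome_set_hint = NULL) {
  Gs <- if (is.null(genome_set_hint)) forest_genome_set(forest) else
    sort(genome_set_hint)
  if (!length(Gs)) stop("empty genome set")
  rec <- function(f, gs) {
    if (length(gs) == 1) return(leaf_tree(gs))
    f <- restrict_forest(f, gs)
    lv <- compute_levels(f)$levels
    edges <- if (length(lv)) {
      build_level_hypergraph(lv[[1]], f)$edges
    } else list()
    memb <- structure(seq_along(gs), names = gs)   # union-find by relabel
    for (e in edges) {
      ids <- unique(memb[e])
      if (length(ids) > 1) memb[memb %in% ids] <- ids[1]
    }
    comps <- split(gs, memb)
    if (length(comps) == 1) return(NULL)
    comps <- comps[order(vapply(comps, min, ""))]
    subs <- lapply(comps, function(cs) rec(f, cs))
    if (any(vapply(subs, is.null, TRUE))) return(NULL)
    Reduce(join_trees, subs)
  }
  st <- rec(forest, Gs)
  if (is.null(st)) return(NULL)
  ## soundness certificate: every duplication under S* is apparent
  for (t in restrict_forest(forest, Gs)) {
    if (duplication_cost(t, st) != sum(ad_flags(t)$ad)) return(NULL)
  }
  st
}
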