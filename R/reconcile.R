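## Genome sets are represented as bitmasks over the species universe of S:
## integer vectors of 30-bit words, combined with bitwAnd / bitwOr.  The
## LCA of a genome set in S is the species vertex with the smallest
## subtree whose mask contains it.

BITS <- 30L

species_info <- function(s) {
  check_species_tree(s)
  univ <- genome_set(s)
  nw <- max(1L, ceiling(length(univ) / BITS))
  word <- ((match(univ, univ) - 1L) %/% BITS) + 1L
  bit <- (match(univ, univ) - 1L) %% BITS
  label_mask <- function(lab) {
    i <- match(lab, univ)
    m <- integer(nw)
    m[word[i]] <- bitwShiftL(1L, bit[i])
    m
  }
  mask <- vector("list", s$n)
  card <- integer(s$n)
  po <- postorder(s)
  for (v in po) {
    if (is_leaf(s, v)) {
      mask[[v]] <- label_mask(s$label[v])
      card[v] <- 1L
    } else {
      mask[[v]] <- bitwOr(mask[[s$kids[v, 1]]], mask[[s$kids[v, 2]]])
      card[v] <- card[s$kids[v, 1]] + card[s$kids[v, 2]]
    }
  }
  leaf_of_label <- structure(leaf_nodes(s),
                             names = s$label[leaf_nodes(s)])
  bykey <- structure(seq_len(s$n),
                     names = vapply(mask, paste, "", collapse = ","))
  structure(list(tree = s, univ = univ, nw = nw, mask = mask, card = card,
                 bysize = order(card), depth = node_depths(s),
                 leaf_of_label = leaf_of_label, bykey = bykey),
            class = "species_info")
}

## Most reconcile functions accept either a species tree or a prebuilt
## species_info (precompute once when mapping many gene trees against the
## same S).
as_species_info <- function(s) {
  if (inherits(s, "species_info")) s else species_info(s)
}

lca_lookup <- function(info, m) {
  for (v in info$bysize) {
    if (all(bitwAnd(info$mask[[v]], m) == m)) return(v)
  }
  stop("internal error: genome set outside the species universe")
}

## Core LCA-mapping pass shared by the reconcile module: per-node species
## mapping M, genome-set masks, duplication and AD/NAD flags.
recon_core <- function(t, info) {
  M <- integer(t$n)
  mask <- vector("list", t$n)
  inter <- logical(t$n)
  for (v in postorder(t)) {
    if (is_leaf(t, v)) {
      i <- info$leaf_of_label[t$label[v]]
      if (is.na(i))
        stop("gene leaf label '", t$label[v], "' absent from the species tree")
      M[v] <- i
      mask[[v]] <- info$mask[[i]]
    } else {
      l <- t$kids[v, 1]; r <- t$kids[v, 2]
      mask[[v]] <- bitwOr(mask[[l]], mask[[r]])
      M[v] <- lca_lookup(info, mask[[v]])
      inter[v] <- any(bitwAnd(mask[[l]], mask[[r]]) != 0L)
    }
  }
  internal <- !is.na(t$kids[, 1])
  dup <- logical(t$n)
  dup[internal] <- M[t$kids[internal, 1]] == M[internal] |
    M[t$kids[internal, 2]] == M[internal]
  list(M = M, mask = mask, dup = dup, inter = inter, internal = internal)
}

#' LCA mapping of a gene tree into a species tree
#'
#' Maps every vertex of `t` to the lowest common ancestor in `s` of its
#' genome set.
#'
#' @param t gene tree (`gtree`); its labels must all occur in `s`.
#' @param s species tree (`gtree`, uniquely leaf-labelled).
#' @return integer vector over the nodes of `t`, giving for each the node
#'   index of its image in `s`.
#' @export
lca_map <- function(t, s) {
  recon_core(t, as_species_info(s))$M
}

#' Classify the internal vertices of a gene tree
#'
#' Under the LCA mapping a vertex is a duplication iff it maps to the same
#' species vertex as one of its children. Duplications whose child genome
#' sets intersect are apparent duplications (AD) -- they are duplications
#' under *every* species tree; duplications with disjoint child genome
#' sets are non-apparent duplications (NAD) and flag a species triplet
#' split differently by the gene tree and the species tree (see
#' [wrong_triplet()]).
#'
#' @inheritParams lca_map
#' @return an object of class `event_table`: data frame `$events` with one
#'   row per internal vertex (node, uid, mapping, event), plus counts
#'   `$dup_count` (d(T,S)), `$ad_count`, `$nad_count`.
#' @export
classify_events <- function(t, s) {
  info <- as_species_info(s)
  rc <- recon_core(t, info)
  nodes <- which(rc$internal)
  event <- ifelse(!rc$dup[nodes], "SPECIATION",
                  ifelse(rc$inter[nodes], "AD", "NAD"))
  out <- list(events = data.frame(node = nodes, uid = t$uid[nodes],
                                  mapping = rc$M[nodes], event = event,
                                  stringsAsFactors = FALSE),
              dup_count = sum(rc$dup), ad_count = sum(event == "AD"),
              nad_count = sum(event == "NAD"),
              M = rc$M, dup = rc$dup, inter = rc$inter)
  class(out) <- "event_table"
  out
}

#' @export
print.event_table <- function(x, ...) {
  print(x$events)
  cat(sprintf("d(T,S) = %d  (AD %d, NAD %d)\n",
              x$dup_count, x$ad_count, x$nad_count))
  invisible(x)
}

#' Duplication, loss and mutation costs of the LCA reconciliation
#'
#' The loss cost charges, for each gene-tree edge (p,u), one loss per
#' species vertex strictly between M(p) and M(u), plus one at M(p) itself
#' when p is a duplication; no loss is charged above the gene-tree root.
#' This equals the number of subtrees grafted by [build_reconciliation()].
#' The mutation cost is d(T,S) plus the loss cost.
#'
#' @inheritParams lca_map
#' @export
loss_cost <- function(t, s) {
  info <- as_species_info(s)
  rc <- recon_core(t, info)
  total <- 0L
  for (u in seq_len(t$n)) {
    p <- t$parent[u]
    if (is.na(p)) next
    total <- total + info$depth[rc$M[u]] - info$depth[rc$M[p]] - 1L +
      as.integer(rc$dup[p])
  }
  total
}

#' @rdname loss_cost
#' @export
duplication_cost <- function(t, s) classify_events(t, s)$dup_count

#' @rdname loss_cost
#' @export
mutation_cost <- function(t, s) {
  info <- as_species_info(s)
  duplication_cost(t, info) + loss_cost(t, info)
}

#' Build the LCA reconciliation as a DS-consistent extension
#'
#' Extends the gene tree by grafting, for every edge (p,u), a copy of the
#' species subtree lost at each species vertex between M(p) and M(u); each
#' grafted subtree represents a gene loss. Removing the grafted subtrees
#' recovers `t` exactly, and the result is DS-consistent with `s`
#' ([is_ds_consistent()]).
#'
#' @inheritParams lca_map
#' @return an object of class `reconciliation`: `$tree` (the extension,
#'   with graft roots recorded in `$tree$graft`), `$losses`, `$dup_count`,
#'   `$mutation_cost`.
#' @export
build_reconciliation <- function(t, s) {
  info <- as_species_info(s)
  s <- info$tree
  rc <- recon_core(t, info)
  r <- t
  r$graft <- integer(0)
  nlosses <- 0L
  for (u in seq_len(t$n)) {
    p <- t$parent[u]
    if (is.na(p)) next
    ## species vertices charged on this edge, top-down
    path <- rc$M[u]
    while (path[1] != rc$M[p]) path <- c(s$parent[path[1]], path)
    charged <- if (rc$dup[p]) path[-length(path)] else
      path[-c(1, length(path))]
    if (!length(charged)) next
    for (i in seq_along(charged)) {
      v <- charged[i]
      below <- path[which(path == v) + 1L]
      off <- setdiff(s$kids[v, ], below)
      r <- graft_on_edge(r, u, subtree_at(s, off))
      nlosses <- nlosses + 1L
    }
  }
  ev <- classify_events(r, s)
  out <- list(tree = r, losses = nlosses, dup_count = rc$dup |> sum(),
              mutation_cost = sum(rc$dup) + nlosses,
              extension_events = ev)
  class(out) <- "reconciliation"
  out
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf("reconciliation: %d duplications, %d losses (mutation cost %d)\n  %s\n",
              x$dup_count, x$losses, x$mutation_cost, write_newick(x$tree)))
  invisible(x)
}

#' Test DS-consistency of a tree with a species tree
#'
#' True iff every vertex covering at least two species has a species
#' vertex with the same genome set and is either a duplication (equal
#' child genome sets) or a speciation (child genome sets equal the species
#' vertex's child genome sets). A tree DS-consistent with `s` reflects a
#' history with no loss.
#'
#' @param r a `gtree` with labels drawn from `s`.
#' @param s species tree.
#' @export
is_ds_consistent <- function(r, s) {
  info <- as_species_info(s)
  s <- info$tree
  mask <- vector("list", r$n)
  for (v in postorder(r)) {
    if (is_leaf(r, v)) {
      i <- info$leaf_of_label[r$label[v]]
      if (is.na(i)) return(FALSE)
      mask[[v]] <- info$mask[[i]]
    } else {
      mask[[v]] <- bitwOr(mask[[r$kids[v, 1]]], mask[[r$kids[v, 2]]])
    }
  }
  for (v in which(!is.na(r$kids[, 1]))) {
    sv <- info$bykey[paste(mask[[v]], collapse = ",")]
    if (is.na(sv)) return(FALSE)       # no species vertex shares the genome set
    if (is_leaf(s, sv)) next           # |L(t)| == 1: unconstrained
    ml <- mask[[r$kids[v, 1]]]; mr <- mask[[r$kids[v, 2]]]
    if (identical(ml, mr)) next        # condition (D)
    sl <- info$mask[[s$kids[sv, 1]]]; sr <- info$mask[[s$kids[sv, 2]]]
    if ((identical(ml, sl) && identical(mr, sr)) ||
        (identical(ml, sr) && identical(mr, sl))) next   # condition (S)
    return(FALSE)
  }
  TRUE
}

#' Test MD-consistency of a gene tree with a species tree
#'
#' True iff every duplication vertex of `t` with respect to `s` is an
#' apparent duplication, i.e. the tree has no NAD vertex
#' (d(T,S) equals the number of apparent duplications).
#'
#' @inheritParams lca_map
#' @export
is_md_consistent <- function(t, s) {
  rc <- recon_core(t, as_species_info(s))
  !any(rc$dup & !rc$inter)
}

#' Wrong species triplet exhibited by a NAD vertex
#'
#' Every NAD vertex splits some species triplet \{a,b,c\} into \{a,b;c\}
#' while the species tree splits it differently -- a phylogenetic
#' contradiction not attributable to duplicated gene copies. Returns the
#' lexicographically smallest such triplet.
#'
#' @inheritParams lca_map
#' @param x node index of a NAD vertex of `t` (per [classify_events()]).
#' @return list with `$triplet` (sorted labels), `$gene_split` and
#'   `$species_split`, each `list(pair =, apart =)`.
#' @export
wrong_triplet <- function(t, s, x) {
  info <- as_species_info(s)
  s <- info$tree
  ev <- classify_events(t, info)
  row <- ev$events[ev$events$node == x, ]
  if (nrow(row) != 1 || row$event != "NAD")
    stop("node ", x, " is not a NAD vertex")
  A <- genome_set(t, t$kids[x, 1])
  B <- genome_set(t, t$kids[x, 2])
  s_pair <- function(tri) {
    l <- lca_lookup(info, Reduce(bitwOr, info$mask[info$leaf_of_label[tri]]))
    left <- genome_set(s, s$kids[l, 1])
    inl <- tri[tri %in% left]
    if (length(inl) == 2) inl else setdiff(tri, inl)
  }
  species <- sort(union(A, B))
  for (tri in utils::combn(species, 3, simplify = FALSE)) {
    pair <- NULL
    for (k in 1:3) {
      p <- tri[-k]; c1 <- tri[k]
      if ((all(p %in% A) && !c1 %in% A && c1 %in% B && !any(p %in% B)) ||
          (all(p %in% B) && !c1 %in% B && c1 %in% A && !any(p %in% A))) {
        pair <- p; apart <- c1; break
      }
    }
    if (is.null(pair)) next
    sp <- s_pair(tri)
    if (!setequal(sp, pair))
      return(list(triplet = tri,
                  gene_split = list(pair = pair, apart = apart),
                  species_split = list(pair = sp, apart = setdiff(tri, sp))))
  }
  stop("internal error: NAD vertex without a wrong triplet")
}
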