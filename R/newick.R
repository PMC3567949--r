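#' Parse a rooted binary tree from a Newick string
#'
#' Leaf labels are species identifiers and may repeat (gene trees); a
#' species tree must additionally be uniquely leaf-labelled (see
#' [check_species_tree()]). A positive integer in a leaf's branch-length
#' slot is read as a leaf weight (weighted-tree dialect, e.g.
#' `"(1:2,2:1);"` gives leaf 1 weight 2); internal branch lengths are
#' ignored. Multifurcations are rejected, not resolved.
#'
#' @param text a semicolon-terminated Newick string.
#' @return a `gtree`.
#' @export
#' @examples
#' parse_newick("((1,2),3);")
parse_newick <- function(text) {
  txt <- trimws(text)
  if (!nzchar(txt) || !endsWith(txt, ";"))
    stop("Newick format error: string must be semicolon-terminated")
  ## single leaf: ape::read.tree cannot represent a one-tip tree
  if (grepl("^[^(),:;]+(:[0-9.]+)?;$", txt)) {
    part <- strsplit(sub(";$", "", txt), ":", fixed = TRUE)[[1]]
    w <- if (length(part) == 2) as.numeric(part[2]) else 1
    tr <- leaf_tree(part[1], w)
    tr$weighted <- length(part) == 2
    return(tr)
  }
  ph <- tryCatch(suppressWarnings(ape::read.tree(text = txt)),
                 error = function(e) NULL)
  if (is.null(ph)) stop("Newick format error: unparseable string")
  phylo_to_gtree(ph)
}

phylo_to_gtree <- function(ph) {
  ntip <- length(ph$tip.label)
  n <- ntip + ph$Nnode
  kids <- matrix(NA_integer_, n, 2)
  for (p in unique(ph$edge[, 1])) {
    ch <- ph$edge[ph$edge[, 1] == p, 2]
    if (length(ch) != 2)
      stop("Newick format error: non-binary vertex with ", length(ch),
           " children (node ", p, ")")
    kids[p, ] <- ch
  }
  label <- c(ph$tip.label, rep(NA_character_, ph$Nnode))
  if (any(is.na(label[seq_len(ntip)]) | label[seq_len(ntip)] == ""))
    stop("Newick format error: empty leaf label")
  weight <- rep(NA_real_, n)
  weighted <- FALSE
  if (!is.null(ph$edge.length)) {
    tipe <- ph$edge[, 2] <= ntip
    weight[ph$edge[tipe, 2]] <- ph$edge.length[tipe]
    weighted <- any(!is.na(weight[seq_len(ntip)]))
  }
  weight[seq_len(ntip)][is.na(weight[seq_len(ntip)])] <- 1
  if (any(weight[seq_len(ntip)] < 1 | weight[seq_len(ntip)] !=
          floor(weight[seq_len(ntip)])))
    stop("Newick format error: leaf weights must be positive integers")
  new_gtree(kids, label, weight, weighted = weighted)
}

#' Serialize a tree to canonical Newick
#'
#' Children are ordered lexicographically by the smallest leaf label in
#' each subtree, so equal trees serialize identically;
#' `parse_newick(write_newick(t))` is isomorphic to `t`. Weighted trees
#' emit leaf weights in the branch-length slot. Roots of loss subtrees
#' grafted by [build_reconciliation()] are serialized with a `LOSS_`
#' prefix on their (leaf or internal) label.
#'
#' @param t a `gtree`.
#' @return a Newick string.
#' @export
write_newick <- function(t) {
  grafts <- t$graft
  minlab <- character(t$n)
  for (v in postorder(t)) {
    minlab[v] <- if (is_leaf(t, v)) t$label[v] else
      min(minlab[t$kids[v, 1]], minlab[t$kids[v, 2]])
  }
  rec <- function(v) {
    pre <- if (v %in% grafts) "LOSS_" else ""
    if (is_leaf(t, v)) {
      w <- if (t$weighted) paste0(":", format(t$weight[v])) else ""
      return(paste0(pre, t$label[v], w))
    }
    ch <- t$kids[v, ]
    if (minlab[ch[2]] < minlab[ch[1]]) ch <- rev(ch)
    paste0("(", rec(ch[1]), ",", rec(ch[2]), ")", if (nzchar(pre)) "LOSS" else "")
  }
  paste0(rec(t$root), ";")
}

#' Validate a species tree
#'
#' A species tree is a `gtree` whose leaf labels are all distinct.
#' @param s a `gtree`.
#' @return `s`, invisibly; errors if a label repeats.
#' @export
check_species_tree <- function(s) {
  lab <- s$label[!is.na(s$label)]
  if (anyDuplicated(lab))
    stop("not a species tree: repeated leaf label ",
         lab[duplicated(lab)][1])
  invisible(s)
}

#' Read / write a forest of gene trees
#'
#' Forest files carry one Newick tree per line. On reading, trees with
#' fewer than two leaves are dropped (a tree with at most two leaves is
#' consistent with every species tree, so it constrains nothing); use
#' `drop_small = FALSE` to keep them.
#'
#' @param path file path.
#' @param drop_small drop trees of size <= 1 (default `TRUE`).
#' @return a list of `gtree` objects.
#' @export
read_forest <- function(path, drop_small = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  f <- lapply(lines, parse_newick)
  if (drop_small) f <- f[vapply(f, tree_size, 0L) > 1]
  f
}

#' @rdname read_forest
#' @param forest list of `gtree`.
#' @export
write_forest <- function(forest, path) {
  writeLines(vapply(forest, write_newick, ""), path)
}

#' @rdname read_forest
#' @export
forest_size <- function(forest) sum(vapply(forest, tree_size, 0L))

#' @rdname read_forest
#' @export
forest_genome_set <- function(forest) {
  sort(unique(unlist(lapply(forest, genome_set))))
}
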