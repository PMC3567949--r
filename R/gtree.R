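#' Rooted binary leaf-labelled trees
#'
#' `gtree` is the package's container for rooted binary trees: gene trees
#' (leaf labels are species identifiers and may repeat) and species trees
#' (labels unique). Nodes are integers `1..n`; internal nodes have exactly
#' two children. Each leaf carries a positive integer weight (1 unless the
#' tree is a weighted tree in the sense of the agreement module) and every
#' node a stable identifier `uid` that survives leaf removal and
#' restriction, so that removed leaves can be reported unambiguously even
#' when labels repeat.
#'
#' @param kids integer matrix `n x 2`; row `v` holds the children of `v`,
#'   `NA` for leaves.
#' @param label character of length `n`; species label per leaf, `NA` for
#'   internal nodes.
#' @param weight numeric leaf weights (`NA` internal); defaults to 1.
#' @param uid stable node identifiers; defaults to `1:n`.
#' @param weighted logical; if `TRUE` the tree serializes in the weighted
#'   dialect (leaf weights in the branch-length slot).
#' @return an object of class `gtree`.
#' @keywords internal
new_gtree <- function(kids, label, weight = NULL, uid = NULL, weighted = FALSE) {
  n <- length(label)
  stopifnot(is.matrix(kids), nrow(kids) == n, ncol(kids) == 2)
  if (is.null(weight)) weight <- ifelse(is.na(kids[, 1]), 1, NA_real_)
  if (is.null(uid)) uid <- seq_len(n)
  parent <- rep(NA_integer_, n)
  ch <- as.vector(t(kids))
  pa <- rep(seq_len(n), each = 2)
  ok <- !is.na(ch)
  if (anyDuplicated(ch[ok])) stop("malformed tree: node with two parents")
  parent[ch[ok]] <- pa[ok]
  root <- which(is.na(parent))
  if (length(root) != 1) stop("malformed tree: tree must have exactly one root")
  leaf <- is.na(kids[, 1])
  if (any(leaf != is.na(kids[, 2]))) stop("malformed tree: unary vertex")
  if (any(is.na(label[leaf]) | label[leaf] == "")) stop("malformed tree: empty leaf label")
  if (any(!is.na(label[!leaf]) & nzchar(label[!leaf]))) label[!leaf] <- NA_character_
  w <- weight[leaf]
  if (any(is.na(w) | w < 1 | w != floor(w))) stop("leaf weights must be positive integers")
  structure(list(kids = kids, parent = parent, label = label,
                 weight = weight, uid = as.integer(uid), root = root,
                 n = n, weighted = isTRUE(weighted)),
            class = "gtree")
}

is_gtree <- function(x) inherits(x, "gtree")

#' @rdname new_gtree
#' @param t a `gtree`.
#' @export
tree_size <- function(t) sum(is.na(t$kids[, 1]))

leaf_nodes <- function(t) which(is.na(t$kids[, 1]))

is_leaf <- function(t, v) is.na(t$kids[v, 1])

#' Build a leaf or join two subtrees (programmatic construction)
#'
#' @param label species label of the leaf.
#' @param weight leaf weight (default 1).
#' @export
leaf_tree <- function(label, weight = 1) {
  new_gtree(matrix(NA_integer_, 1, 2), as.character(label), weight,
            weighted = !missing(weight) && weight != 1)
}

#' @rdname leaf_tree
#' @param a,b `gtree` subtrees to join under a new root.
#' @export
join_trees <- function(a, b) {
  off <- a$n
  kids <- rbind(a$kids, b$kids + off, c(a$root, b$root + off))
  label <- c(a$label, b$label, NA_character_)
  weight <- c(a$weight, b$weight, NA_real_)
  new_gtree(kids, label, weight,
            uid = seq_len(a$n + b$n + 1L),
            weighted = a$weighted || b$weighted)
}

#' Post-order traversal of the node indices
#' @keywords internal
postorder <- function(t) {
  out <- integer(t$n); k <- t$n
  stack <- t$root
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out[k] <- v; k <- k - 1L
    if (!is.na(t$kids[v, 1])) stack <- c(stack, t$kids[v, 1], t$kids[v, 2])
  }
  out
}

node_depths <- function(t) {
  d <- integer(t$n)
  for (v in rev(postorder(t))) {      # preorder
    p <- t$parent[v]
    d[v] <- if (is.na(p)) 0L else d[p] + 1L
  }
  d
}

subtree_nodes <- function(t, v) {
  out <- integer(0); stack <- v
  while (length(stack)) {
    x <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    out <- c(out, x)
    if (!is.na(t$kids[x, 1])) stack <- c(stack, t$kids[x, 1], t$kids[x, 2])
  }
  out
}

#' Extract the subtree rooted at a node
#'
#' Stable identifiers, labels and weights are preserved.
#' @param t a `gtree`.
#' @param v node index in `t`.
#' @export
subtree_at <- function(t, v) {
  nodes <- sort(subtree_nodes(t, v))
  remap <- integer(t$n); remap[nodes] <- seq_along(nodes)
  kids <- t$kids[nodes, , drop = FALSE]
  kids[!is.na(kids)] <- remap[kids[!is.na(kids)]]
  new_gtree(kids, t$label[nodes], t$weight[nodes], t$uid[nodes],
            weighted = t$weighted)
}

#' Genome set of a subtree
#'
#' The set (not multiset) of species labels carried by the leaves below
#' `v`, sorted lexicographically.
#' @param t a `gtree`.
#' @param v node index (default: root).
#' @export
genome_set <- function(t, v = t$root) {
  nodes <- subtree_nodes(t, v)
  sort(unique(t$label[nodes][!is.na(t$label[nodes])]))
}

## Rebuild the tree keeping only the flagged leaves, suppressing the
## resulting unary vertices.  Returns NULL when no leaf survives.
rebuild_from <- function(t, keep) {
  n <- t$n
  kidsL <- integer(n); kidsR <- integer(n)
  lab <- character(n); wt <- numeric(n); uid <- integer(n)
  cnt <- 0L
  rec <- function(v) {
    if (is.na(t$kids[v, 1])) {
      if (!keep[v]) return(0L)
      cnt <<- cnt + 1L
      kidsL[cnt] <<- NA_integer_; kidsR[cnt] <<- NA_integer_
      lab[cnt] <<- t$label[v]; wt[cnt] <<- t$weight[v]; uid[cnt] <<- t$uid[v]
      return(cnt)
    }
    a <- rec(t$kids[v, 1]); b <- rec(t$kids[v, 2])
    if (a == 0L && b == 0L) return(0L)
    if (a == 0L) return(b)
    if (b == 0L) return(a)
    cnt <<- cnt + 1L
    kidsL[cnt] <<- a; kidsR[cnt] <<- b
    lab[cnt] <<- NA_character_; wt[cnt] <<- NA_real_; uid[cnt] <<- t$uid[v]
    cnt
  }
  r <- rec(t$root)
  if (r == 0L) return(NULL)
  idx <- seq_len(cnt)
  new_gtree(cbind(kidsL[idx], kidsR[idx]), lab[idx], wt[idx], uid[idx],
            weighted = t$weighted)
}

#' Remove a single leaf
#'
#' Deletes the leaf and its parent, joining the grandparent to the sibling;
#' if the parent was the root the sibling becomes the new root.
#' @param t a `gtree` with at least two leaves.
#' @param leaf index of a leaf node of `t`.
#' @export
remove_leaf <- function(t, leaf) {
  if (!is_leaf(t, leaf)) stop("node ", leaf, " is not a leaf")
  if (tree_size(t) < 2) stop("cannot remove the last leaf of a tree")
  keep <- is.na(t$kids[, 1])
  keep[leaf] <- FALSE
  rebuild_from(t, keep)
}

#' Restrict a tree to a subset of species
#'
#' Removes every leaf whose label lies outside `keep` by iterated leaf
#' removal. Returns `NULL` when no leaf survives.
#' @param t a `gtree`.
#' @param keep character vector of species labels to retain.
#' @export
restrict_to <- function(t, keep) {
  k <- is.na(t$kids[, 1]) & t$label %in% keep
  if (!any(k)) return(NULL)
  rebuild_from(t, k)
}

## Replace the subtree rooted at v by `sub` (fresh uids for sub's nodes).
replace_subtree <- function(t, v, sub) {
  if (v == t$root) return(sub)
  drop <- subtree_nodes(t, v)
  keepn <- setdiff(seq_len(t$n), drop)
  remap <- integer(t$n); remap[keepn] <- seq_along(keepn)
  kids <- t$kids[keepn, , drop = FALSE]
  nz <- !is.na(kids)
  kids[nz] <- remap[kids[nz]]
  off <- length(keepn)
  subroot <- off + sub$root
  p <- remap[t$parent[v]]
  kids[p, ][t$kids[t$parent[v], ] == v] <- subroot
  kids <- rbind(kids, sub$kids + off)
  maxuid <- max(t$uid)
  new_gtree(kids,
            c(t$label[keepn], sub$label),
            c(t$weight[keepn], sub$weight),
            c(t$uid[keepn], maxuid + sub$uid),
            weighted = t$weighted || sub$weighted)
}

## Graft `sub` onto the edge above `child` (or above the root), creating a
## new internal vertex.  `graft` grafts are tracked via the "graft" field
## (root indices of inserted subtrees) used by the reconciliation module.
graft_on_edge <- function(t, child, sub, mark = FALSE) {
  off <- t$n
  kids <- rbind(t$kids, sub$kids + off)
  z <- off + sub$n + 1L
  kids <- rbind(kids, c(child, off + sub$root))
  maxuid <- max(t$uid)
  if (child != t$root) {
    p <- t$parent[child]
    kids[p, ][t$kids[p, ] == child] <- z
  }
  out <- new_gtree(kids,
                   c(t$label, sub$label, NA_character_),
                   c(t$weight, sub$weight, NA_real_),
                   c(t$uid, maxuid + sub$uid, maxuid + sub$n + 1L),
                   weighted = t$weighted)
  out$graft <- c(t$graft, off + sub$root)
  out
}

#' @export
print.gtree <- function(x, ...) {
  cat(sprintf("gtree: %d leaves, %d species%s\n  %s\n",
              tree_size(x), length(genome_set(x)),
              if (x$weighted) ", weighted" else "",
              write_newick(x)))
  invisible(x)
}
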