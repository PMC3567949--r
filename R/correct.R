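## Gene-tree correction against a known species tree: collapse apparent
## duplications into weighted leaves, solve weighted maximum agreement
## subtrees on the NAD-bearing parts, and restrict the gene tree to the
## surviving species, repeating until no non-apparent duplication is left.

## species-tree-free AD flags (intersecting child genome sets) and the
## "AD somewhere below" closure, via label sets
ad_flags <- function(t) {
  ls <- label_sets(t)
  ad <- logical(t$n); below <- logical(t$n)
  for (v in postorder(t)) {
    if (!is_leaf(t, v)) {
      l <- t$kids[v, 1]; r <- t$kids[v, 2]
      ad[v] <- length(intersect(ls[[l]], ls[[r]])) > 0
      below[v] <- ad[v] || below[l] || below[r]
    }
  }
  list(ad = ad, below = below)
}

## preorder (left-to-right) antichain of highest nodes satisfying `take`;
## descend where `descend` allows
antichain <- function(t, take) {
  out <- integer(0)
  rec <- function(v) {
    if (take[v]) { out <<- c(out, v); return(invisible()) }
    if (!is_leaf(t, v)) { rec(t$kids[v, 1]); rec(t$kids[v, 2]) }
  }
  rec(t$root)
  out
}

#' AD-border and NAD-border of a gene tree
#'
#' The AD-border is the antichain of highest vertices that are apparent
#' duplications whose subtree contains no NAD vertex (Property ONLY-AD);
#' these are the subtrees collapsed into weighted leaves by [build_ti()].
#' The NAD-border is the antichain of highest vertices whose subtree
#' contains no AD vertex (Property ONLY-NAD); these are the subtrees
#' handed to [wmast()] by [correct_tree()].
#'
#' @param t gene tree (for [ad_border()]) or annotated/weighted tree (for
#'   [nad_border()], which needs no species tree: AD-ness depends only on
#'   the gene tree).
#' @param s species tree.
#' @return integer vector of node indices (left-to-right order).
#' @export
ad_border <- function(t, s) {
  info <- as_species_info(s)
  rc <- recon_core(t, info)
  nad <- rc$dup & !rc$inter
  hasnad <- logical(t$n)
  for (v in postorder(t)) {
    if (!is_leaf(t, v))
      hasnad[v] <- nad[v] || hasnad[t$kids[v, 1]] || hasnad[t$kids[v, 2]]
  }
  af <- ad_flags(t)
  antichain(t, af$ad & !hasnad)
}

#' @rdname ad_border
#' @export
nad_border <- function(t) {
  af <- ad_flags(t)
  antichain(t, !af$below)
}

#' Weighted tree induced by a gene (sub)tree and the species tree
#'
#' The species tree restricted to the genome set of `u`, with each leaf
#' weighted by the number of gene copies of that species in `u` (summing
#' leaf weights when `u` itself is weighted). Its value v(W) always
#' equals the (weighted) leaf count of `u`.
#'
#' @param u a `gtree` with labels drawn from `s`.
#' @param s species tree.
#' @return a uniquely leaf-labelled weighted `gtree`.
#' @export
induced_weighted_tree <- function(u, s) {
  lv <- leaf_nodes(u)
  occ <- tapply(u$weight[lv], u$label[lv], sum)
  w <- restrict_to(s, names(occ))
  w$weight[leaf_nodes(w)] <- as.numeric(occ[w$label[leaf_nodes(w)]])
  w$weighted <- TRUE
  w$uid <- seq_len(w$n)
  w
}

#' Collapse apparent duplications: the annotated tree T^I
#'
#' Replaces every AD-border subtree by its induced weighted tree, and
#' repeats the replacement if the collapse itself creates new ONLY-AD
#' subtrees (possible when two collapsed regions under a common ancestor
#' share species -- a situation that only arises when an AD vertex sits
#' above a NAD vertex). The result carries, for each node, the stable
#' identifier of the corresponding vertex of `t` (`NA` inside replaced
#' regions, whose shape comes from `s`).
#'
#' @inheritParams ad_border
#' @return list with `$tree` (weighted `gtree`) and `$orig_uid`.
#' @export
build_ti <- function(t, s) {
  info <- as_species_info(s)
  ti <- t
  ouid <- t$uid
  repeat {
    border <- ad_border(ti, info)
    if (!length(border)) break
    res <- collapse_regions(ti, ouid, border, info)
    ti <- res$tree; ouid <- res$orig_uid
  }
  list(tree = ti, orig_uid = ouid)
}

collapse_regions <- function(t, ouid, border, info) {
  kidsL <- integer(0); kidsR <- integer(0)
  lab <- character(0); wt <- numeric(0); ou <- integer(0)
  add <- function(l, r, la, w, o) {
    kidsL <<- c(kidsL, l); kidsR <<- c(kidsR, r)
    lab <<- c(lab, la); wt <<- c(wt, w); ou <<- c(ou, o)
    length(kidsL)
  }
  add_tree <- function(sub, root_ouid) {
    remap <- integer(sub$n)
    for (v in postorder(sub)) {
      o <- if (v == sub$root) root_ouid else NA_integer_
      remap[v] <- if (is_leaf(sub, v))
        add(NA_integer_, NA_integer_, sub$label[v], sub$weight[v], o)
      else add(remap[sub$kids[v, 1]], remap[sub$kids[v, 2]],
               NA_character_, NA_real_, o)
    }
    remap[sub$root]
  }
  rec <- function(v) {
    if (v %in% border)
      return(add_tree(induced_weighted_tree(subtree_at(t, v), info$tree),
                      ouid[v]))
    if (is_leaf(t, v))
      return(add(NA_integer_, NA_integer_, t$label[v], t$weight[v], ouid[v]))
    a <- rec(t$kids[v, 1]); b <- rec(t$kids[v, 2])
    add(a, b, NA_character_, NA_real_, ouid[v])
  }
  r <- rec(t$root)
  tree <- new_gtree(cbind(kidsL, kidsR), lab, wt, weighted = TRUE)
  stopifnot(tree$root == r)
  list(tree = tree, orig_uid = ou)
}

#' Does a gene tree keep all apparent duplications below its NADs?
#'
#' True iff no AD vertex is a proper ancestor of a NAD vertex (Constraint
#' C). On such trees -- and on uniquely leaf-labelled trees, where the
#' condition holds vacuously -- [correct_tree()] is exact.
#'
#' @inheritParams ad_border
#' @export
satisfies_constraint_c <- function(t, s) {
  info <- as_species_info(s)
  rc <- recon_core(t, info)
  nad <- rc$dup & !rc$inter
  ad <- rc$dup & rc$inter
  hasnad <- logical(t$n)
  for (v in postorder(t)) {
    if (!is_leaf(t, v)) {
      l <- t$kids[v, 1]; r <- t$kids[v, 2]
      hasnad[v] <- hasnad[l] || hasnad[r] || nad[l] || nad[r]
    }
  }
  !any(ad & hasnad)
}

md_consistent_fast <- function(t, info) {
  rc <- recon_core(t, info)
  !any(rc$dup & !rc$inter)
}

#' Correct a gene tree by minimum leaf removal (Correct-Tree)
#'
#' Removes leaves from `t` until it is MD-consistent with `s` (no NAD
#' vertex left). Each pass collapses the AD-border into weighted leaves
#' ([build_ti()]), solves a weighted maximum agreement subtree on every
#' NAD-border subtree, and restricts the gene tree to the surviving
#' species of each; dropping a weighted leaf removes all copies of that
#' species in the region. Exact (minimum removal count) when `t` is
#' uniquely leaf-labelled or satisfies Constraint C; a heuristic
#' otherwise, with `N >= N_opt` always ([exact_min_removals()]).
#'
#' @inheritParams ad_border
#' @return a `correction_report`: `$removals` (count N), `$removed_leaves`
#'   (data frame: uid, label -- uids are stable identifiers of `t`),
#'   `$corrected` (MD-consistent `gtree`), `$iterations` (recursive
#'   passes).
#' @export
correct_tree <- function(t, s) {
  info <- as_species_info(s)
  cur <- t
  removed_uid <- integer(0); removed_lab <- character(0)
  iterations <- 0L
  repeat {
    if (md_consistent_fast(cur, info)) break
    iterations <- iterations + 1L
    ti <- build_ti(cur, info)
    drop <- logical(cur$n)
    for (x in nad_border(ti$tree)) {
      sub <- subtree_at(ti$tree, x)
      if (tree_size(sub) < 2) next
      if (md_consistent_fast(sub, info)) next
      res <- wmast(sub, info$tree)
      cx <- match(ti$orig_uid[x], cur$uid)
      nodes <- subtree_nodes(cur, cx)
      bad <- nodes[!is.na(cur$label[nodes]) &
                     !(cur$label[nodes] %in% res$kept_leaves)]
      drop[bad] <- TRUE
    }
    if (!any(drop))
      stop("internal error: correction pass removed no leaves")
    removed_uid <- c(removed_uid, cur$uid[drop])
    removed_lab <- c(removed_lab, cur$label[drop])
    cur <- rebuild_from(cur, is.na(cur$kids[, 1]) & !drop)
  }
  structure(list(removals = length(removed_uid),
                 removed_leaves = data.frame(uid = removed_uid,
                                             label = removed_lab,
                                             stringsAsFactors = FALSE),
                 corrected = cur, iterations = iterations),
            class = "correction_report")
}

#' @export
print.correction_report <- function(x, ...) {
  cat(sprintf("correction: %d leaf removal(s) in %d pass(es)\n",
              x$removals, x$iterations))
  if (x$removals)
    cat("  removed:", paste(sprintf("%s(uid %d)", x$removed_leaves$label,
                                    x$removed_leaves$uid), collapse = ", "),
        "\n")
  cat("  corrected:", write_newick(x$corrected), "\n")
  invisible(x)
}

#' Correct every tree of a forest
#'
#' @param forest list of `gtree`.
#' @inheritParams ad_border
#' @return a `correction_report` whose `$corrected` is a forest and whose
#'   `$removed_leaves` gains a `tree` (index) column.
#' @export
correct_forest <- function(forest, s) {
  info <- as_species_info(s)
  reps <- lapply(forest, correct_tree, s = info)
  rem <- do.call(rbind, lapply(seq_along(reps), function(i) {
    d <- reps[[i]]$removed_leaves
    if (!nrow(d)) return(NULL)
    cbind(tree = i, d)
  }))
  if (is.null(rem))
    rem <- data.frame(tree = integer(0), uid = integer(0),
                      label = character(0))
  structure(list(removals = sum(vapply(reps, `[[`, 0L, "removals")),
                 removed_leaves = rem,
                 corrected = lapply(reps, `[[`, "corrected"),
                 iterations = max(vapply(reps, `[[`, 0L, "iterations"))),
            class = "correction_report")
}

#' Exhaustive minimum leaf removal (optimality oracle)
#'
#' Searches leaf subsets of increasing size k = 0, 1, 2, ... and returns
#' the smallest k whose removal leaves the tree MD-consistent with `s`,
#' together with one witness subset. The search is bounded above by
#' [correct_tree()]'s removal count, so it always terminates; `cap`
#' limits the number of subsets examined.
#'
#' @inheritParams ad_border
#' @param cap maximum number of candidate subsets to test.
#' @return list with `$n_opt`, `$removed` (data frame uid, label) and
#'   `$corrected`.
#' @export
exact_min_removals <- function(t, s, cap = 2e6) {
  info <- as_species_info(s)
  if (md_consistent_fast(t, info))
    return(list(n_opt = 0L,
                removed = data.frame(uid = integer(0), label = character(0)),
                corrected = t))
  ub <- correct_tree(t, info)$removals
  leaves <- leaf_nodes(t)
  tried <- 0
  for (k in seq_len(ub)) {
    for (rem in utils::combn(leaves, k, simplify = FALSE)) {
      tried <- tried + 1
      if (tried > cap)
        stop("exact search space exceeds cap = ", cap, " subsets")
      keep <- is.na(t$kids[, 1]); keep[rem] <- FALSE
      red <- rebuild_from(t, keep)
      if (!is.null(red) && tree_size(red) >= 1 &&
          md_consistent_fast(red, info)) {
        return(list(n_opt = k,
                    removed = data.frame(uid = t$uid[rem],
                                         label = t$label[rem],
                                         stringsAsFactors = FALSE),
                    corrected = red))
      }
    }
  }
  stop("internal error: heuristic bound not met by exhaustive search")
}

#' Minimum species removal against a known species tree
#'
#' For a gene tree satisfying Constraint C, an unweighted MAST on the
#' collapsed tree T^I gives the largest species subset on which `t` can
#' be made MD-consistent with the corresponding restriction of `s`.
#'
#' @inheritParams ad_border
#' @return list with `$removed_species`, `$kept_species`, `$corrected`
#'   (the restriction of `t`).
#' @export
min_species_removal_correct <- function(t, s) {
  info <- as_species_info(s)
  if (!satisfies_constraint_c(t, info))
    stop("tree has an AD vertex above a NAD vertex; use the species-",
         "removal reduction through minimum_species_removal_inference()")
  ti <- build_ti(t, info)
  res <- mast(ti$tree, info$tree)
  kept <- res$kept_leaves
  corrected <- restrict_to(t, kept)
  srs <- restrict_to(info$tree, kept)
  if (!is_md_consistent(corrected, srs))
    stop("internal error: species-removal result not MD-consistent")
  list(removed_species = setdiff(genome_set(t), kept),
       kept_species = kept, corrected = corrected)
}
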