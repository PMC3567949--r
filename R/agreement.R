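## Rooted maximum agreement subtree between two binary trees, by the
## classical quadratic dynamic program over subtree pairs, generalized to
## weighted leaves (the leaf base case scores the leaf weight instead of
## 1).  Ties between equal-score kept sets are broken per DP cell towards
## the lexicographically smaller sorted label set, which makes the
## reported witness deterministic.

set_less <- function(a, b) {
  la <- length(a); lb <- length(b)
  for (i in seq_len(min(la, lb))) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  la < lb
}

label_sets <- function(t) {
  ls <- vector("list", t$n)
  for (v in postorder(t)) {
    ls[[v]] <- if (is_leaf(t, v)) t$label[v] else
      sort(unique(c(ls[[t$kids[v, 1]]], ls[[t$kids[v, 2]]])))
  }
  ls
}

agreement_dp <- function(w, s, wt) {
  labs <- w$label[!is.na(w$label)]
  if (anyDuplicated(labs))
    stop("agreement input must be uniquely leaf-labelled (repeated label '",
         labs[duplicated(labs)][1], "')")
  Lt <- label_sets(w); Ls <- label_sets(s)
  nS <- s$n
  score <- matrix(0, w$n, nS)
  kept <- vector("list", w$n * nS)
  idx <- function(tn, sn) (tn - 1L) * nS + sn
  poT <- postorder(w); poS <- postorder(s)
  for (tn in poT) {
    for (sn in poS) {
      if (is_leaf(w, tn)) {
        lab <- w$label[tn]
        if (lab %in% Ls[[sn]]) {
          score[tn, sn] <- wt[lab]
          kept[[idx(tn, sn)]] <- lab
        } else kept[[idx(tn, sn)]] <- character(0)
        next
      }
      if (is_leaf(s, sn)) {
        lab <- s$label[sn]
        if (lab %in% Lt[[tn]]) {
          score[tn, sn] <- wt[lab]
          kept[[idx(tn, sn)]] <- lab
        } else kept[[idx(tn, sn)]] <- character(0)
        next
      }
      tl <- w$kids[tn, 1]; tr <- w$kids[tn, 2]
      sl <- s$kids[sn, 1]; sr <- s$kids[sn, 2]
      cand_sc <- c(score[tl, sl] + score[tr, sr],
                   score[tl, sr] + score[tr, sl],
                   score[tn, sl], score[tn, sr],
                   score[tl, sn], score[tr, sn])
      cand_set <- function(k) switch(k,
        sort(c(kept[[idx(tl, sl)]], kept[[idx(tr, sr)]])),
        sort(c(kept[[idx(tl, sr)]], kept[[idx(tr, sl)]])),
        kept[[idx(tn, sl)]], kept[[idx(tn, sr)]],
        kept[[idx(tl, sn)]], kept[[idx(tr, sn)]])
      best <- max(cand_sc)
      pick <- NULL
      for (k in which(cand_sc == best)) {
        ck <- cand_set(k)
        if (is.null(pick) || set_less(ck, pick)) pick <- ck
      }
      score[tn, sn] <- best
      kept[[idx(tn, sn)]] <- pick
    }
  }
  K <- kept[[idx(w$root, s$root)]]
  structure(list(kept_leaves = K,
                 subtree = if (length(K)) restrict_to(w, K) else NULL,
                 score = score[w$root, s$root]),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("agreement subtree: score %g, kept {%s}\n",
              x$score, paste(x$kept_leaves, collapse = ",")))
  invisible(x)
}

#' Maximum agreement subtree of a gene tree and a species tree
#'
#' Largest set of leaves on which the two rooted trees agree: restricted
#' to the kept set, `t` and `s` are isomorphic as rooted trees
#' (equivalently, the restriction of `t` is MD-consistent with `s`).
#' For a uniquely leaf-labelled gene tree, the minimum-leaf-removal
#' correction is exactly `tree_size(t) - mast(t, s)$score`.
#'
#' @param t uniquely leaf-labelled `gtree` with labels drawn from `s`.
#' @param s species tree.
#' @return an `agreement_result`: `$kept_leaves` (sorted labels),
#'   `$subtree` (the restriction), `$score` (number of kept leaves).
#' @export
mast <- function(t, s) {
  check_species_tree(s)
  labs <- unique(t$label[!is.na(t$label)])
  wt <- structure(rep(1, length(labs)), names = labs)
  agreement_dp(t, s, wt)
}

#' Weighted maximum agreement subtree
#'
#' As [mast()], but each leaf of `w` carries a positive integer weight
#' (the number of gene copies it stands for, see
#' [induced_weighted_tree()]) and the kept set maximizes total weight
#' `v(W^MAX)` rather than leaf count. A weighted leaf is kept or dropped
#' as a whole.
#'
#' @param w uniquely leaf-labelled weighted `gtree`.
#' @param s species tree.
#' @return an `agreement_result` with `$score = v(W^MAX)`.
#' @export
wmast <- function(w, s) {
  check_species_tree(s)
  leaves <- leaf_nodes(w)
  wt <- structure(w$weight[leaves], names = w$label[leaves])
  agreement_dp(w, s, wt)
}

#' Caterpillar expansion of a weighted agreement instance
#'
#' Replaces every leaf `g` of weight `c > 1`, in both the weighted gene
#' tree and the species tree, by the caterpillar
#' `(g#c,(...,(g#2,g#1)...))` over `c` fresh unit leaves. Both outputs are
#' uniquely leaf-labelled, and solving plain MAST on the expansion then
#' collapsing each surviving caterpillar back to one weighted leaf solves
#' the weighted problem -- kept as an independent cross-check of
#' [wmast()] in [wmast_by_expansion()].
#'
#' @inheritParams wmast
#' @return list with `$gene` and `$species`, the two expanded trees.
#' @export
expand_weighted <- function(w, s) {
  caterpillar <- function(lab, c) {
    t <- leaf_tree(paste0(lab, "#1"))
    for (i in seq_len(c)[-1]) t <- join_trees(leaf_tree(paste0(lab, "#", i)), t)
    t
  }
  ge <- w; ge$weighted <- FALSE
  se <- s
  for (lf in leaf_nodes(w)) {
    if (w$weight[lf] > 1) {
      lab <- w$label[lf]; c <- w$weight[lf]
      ge <- replace_subtree(ge, which(ge$label == lab & is.na(ge$kids[, 1]))[1],
                            caterpillar(lab, c))
      se <- replace_subtree(se, which(se$label == lab & is.na(se$kids[, 1]))[1],
                            caterpillar(lab, c))
    }
  }
  ge$weight[is.na(ge$kids[, 1])] <- 1
  se$weight[is.na(se$kids[, 1])] <- 1
  list(gene = ge, species = se)
}

#' @rdname expand_weighted
#' @export
wmast_by_expansion <- function(w, s) {
  ex <- expand_weighted(w, s)
  res <- mast(ex$gene, ex$species)
  base <- sub("#[0-9]+$", "", res$kept_leaves)
  leaves <- leaf_nodes(w)
  full <- structure(w$weight[leaves], names = w$label[leaves])
  cnt <- table(base)
  if (!all(cnt == full[names(cnt)]))
    stop("internal error: MAST kept a proper part of an expanded caterpillar")
  K <- sort(names(cnt))
  structure(list(kept_leaves = K,
                 subtree = if (length(K)) restrict_to(w, K) else NULL,
                 score = sum(full[K])),
            class = "agreement_result")
}
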