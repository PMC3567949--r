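## Seeded generators and the two simulation studies of the correction
## heuristic: optimality against the exhaustive oracle on small trees,
## and detection of randomly inserted (misplaced) leaves.
##
## Random topologies are grown by sequential uniform random-edge
## insertion (each new leaf is grafted onto a uniformly chosen edge,
## including the edge above the root); gene-tree labels are drawn
## uniformly with replacement from the genome set.

#' Random trees and perturbations
#'
#' `random_species_tree` grows a uniformly labelled random topology over
#' the given species; `random_gene_tree` grows a random topology of the
#' given size with labels drawn uniformly with replacement;
#' `random_md_tree` starts from the species tree and applies random leaf
#' duplications (a leaf becomes a cherry of two copies of its label), so
#' the result is always MD-consistent with `s`; `perturb_with_leaves`
#' grafts `k` new leaves with uniform labels onto uniform edges. All are
#' bit-reproducible under `seed`; with `seed = NULL` they consume the
#' current RNG stream.
#'
#' @param species character vector of species labels (at least 2).
#' @param seed optional integer seed.
#' @return a `gtree`.
#' @export
random_species_tree <- function(species, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  species <- as.character(species)
  stopifnot(length(species) >= 2)
  ord <- sample(species)
  t <- join_trees(leaf_tree(ord[1]), leaf_tree(ord[2]))
  for (lab in ord[-(1:2)]) {
    at <- sample.int(t$n, 1)
    t <- graft_on_edge(t, at, leaf_tree(lab))
    t$graft <- NULL
  }
  t$uid <- seq_len(t$n)
  t
}

#' @rdname random_species_tree
#' @param size number of leaves of the gene tree.
#' @export
random_gene_tree <- function(size, species, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  species <- as.character(species)
  stopifnot(size >= 2)
  t <- join_trees(leaf_tree(sample(species, 1)), leaf_tree(sample(species, 1)))
  while (tree_size(t) < size) {
    at <- sample.int(t$n, 1)
    t <- graft_on_edge(t, at, leaf_tree(sample(species, 1)))
    t$graft <- NULL
  }
  t$uid <- seq_len(t$n)
  t
}

#' @rdname random_species_tree
#' @param s species tree to start from.
#' @export
random_md_tree <- function(s, size, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- tree_size(s)
  if (size < g)
    stop("size must be at least the number of species (", g, ")")
  t <- s
  for (i in seq_len(size - g)) {
    lf <- sample(leaf_nodes(t), 1)
    lab <- t$label[lf]
    t <- replace_subtree(t, lf, join_trees(leaf_tree(lab), leaf_tree(lab)))
  }
  t$uid <- seq_len(t$n)
  t$weighted <- FALSE
  t
}

#' @rdname random_species_tree
#' @param t gene tree to perturb.
#' @param k number of leaves to insert.
#' @export
perturb_with_leaves <- function(t, k, species, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  species <- as.character(species)
  stopifnot(k >= 1)
  for (i in seq_len(k)) {
    at <- sample.int(t$n, 1)
    t <- graft_on_edge(t, at, leaf_tree(sample(species, 1)))
    t$graft <- NULL
  }
  t$uid <- seq_len(t$n)
  t
}

#' Optimality study of the correction heuristic
#'
#' For each tree size, generates random gene trees against random species
#' trees over a small genome set, keeps those with an AD vertex above a
#' NAD vertex (on all other trees the heuristic is provably exact), and
#' compares [correct_tree()]'s removal count N with the exhaustive
#' optimum N_opt of [exact_min_removals()].
#'
#' @param genomes number of species.
#' @param sizes gene-tree sizes to scan.
#' @param per_size random trees generated per size (before filtering).
#' @param seed integer seed for the whole experiment.
#' @param cap subset cap forwarded to [exact_min_removals()]; trials
#'   exceeding it are skipped and counted in `$skipped`.
#' @return an `experiment_result`: `$trials` (size, N, N_opt, error
#'   rate), `$summary` per size, `$exact_match_pct`,
#'   `$max_mean_error_rate`.
#' @export
run_optimality_experiment <- function(genomes = 5, sizes = seq(6, 14, 2),
                                      per_size = 100, seed = 1, cap = 2e6) {
  set.seed(seed)
  species <- as.character(seq_len(genomes))
  rows <- list(); skipped <- 0L
  for (s in sizes) {
    for (i in seq_len(per_size)) {
      sp <- random_species_tree(species)
      t <- random_gene_tree(s, species)
      info <- species_info(sp)
      if (satisfies_constraint_c(t, info)) next   # keep AD-above-NAD only
      n <- correct_tree(t, info)$removals
      nopt <- tryCatch(exact_min_removals(t, info, cap = cap)$n_opt,
                       error = function(e) NA_integer_)
      if (is.na(nopt)) { skipped <- skipped + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(size = s, N = n, N_opt = nopt)
    }
  }
  trials <- do.call(rbind, rows)
  trials$error_rate <- (trials$N - trials$N_opt) / trials$N
  summary <- do.call(rbind, lapply(split(trials, trials$size), function(d)
    data.frame(size = d$size[1], n_trials = nrow(d),
               exact_match_pct = 100 * mean(d$N == d$N_opt),
               mean_error_rate = mean(d$error_rate))))
  structure(list(mode = "optimality", seed = seed,
                 model = "sequential uniform random-edge insertion",
                 trials = trials, summary = summary, skipped = skipped,
                 exact_match_pct = 100 * mean(trials$N == trials$N_opt),
                 max_mean_error_rate = max(summary$mean_error_rate)),
            class = "experiment_result")
}

#' Misplaced-leaf detection study
#'
#' For each size s, generates a random species tree, a random
#' MD-consistent gene tree of size s, inserts `s/10` leaves at random
#' (the misplaced genes), and records how many leaves [correct_tree()]
#' removes, as the detection percentage (N / NbAdded) x 100. Perturbed
#' trees that remain MD-consistent yield no removable signal (N = 0);
#' the headline aggregate excludes them, and `$detection_pct_incl`
#' reports the average with them included as zeros.
#'
#' @param genomes number of species.
#' @param sizes gene-tree sizes (NbAdded = size/10, at least 1).
#' @param per_size trials per size.
#' @param seed integer seed.
#' @return an `experiment_result`: `$trials` (size, nb_added, N,
#'   md_consistent, detection_pct), `$summary` per size,
#'   `$detection_pct_excl`, `$detection_pct_incl`.
#' @export
run_detection_experiment <- function(genomes = 10, sizes = seq(10, 100, 10),
                                     per_size = 20, seed = 1) {
  set.seed(seed)
  species <- as.character(seq_len(genomes))
  rows <- list()
  for (s in sizes) {
    k <- max(1L, floor(s / 10))
    for (i in seq_len(per_size)) {
      sp <- random_species_tree(species)
      info <- species_info(sp)
      t <- random_md_tree(sp, s)
      p <- perturb_with_leaves(t, k, species)
      md <- md_consistent_fast(p, info)
      n <- if (md) 0L else correct_tree(p, info)$removals
      rows[[length(rows) + 1L]] <-
        data.frame(size = s, nb_added = k, N = n, md_consistent = md,
                   detection_pct = 100 * n / k)
    }
  }
  trials <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(trials, trials$size), function(d)
    data.frame(size = d$size[1], n_trials = nrow(d),
               n_md_consistent = sum(d$md_consistent),
               detection_pct_incl = mean(d$detection_pct),
               detection_pct_excl =
                 if (any(!d$md_consistent))
                   mean(d$detection_pct[!d$md_consistent]) else NA_real_)))
  structure(list(mode = "detection", seed = seed,
                 model = "sequential uniform random-edge insertion",
                 trials = trials, summary = summary,
                 detection_pct_incl = mean(trials$detection_pct),
                 detection_pct_excl =
                   mean(trials$detection_pct[!trials$md_consistent])),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("%s experiment (seed %d, %d trials)\n", x$mode, x$seed,
              nrow(x$trials)))
  print(x$summary, row.names = FALSE)
  if (x$mode == "optimality")
    cat(sprintf("exact on %.1f%% of trees; max per-size mean error rate %.3f\n",
                x$exact_match_pct, x$max_mean_error_rate))
  else
    cat(sprintf("detection: %.1f%% (excluding MD-consistent), %.1f%% (all)\n",
                x$detection_pct_excl, x$detection_pct_incl))
  invisible(x)
}

#' Write an experiment result as CSV
#'
#' Per-trial rows preceded by `#`-prefixed header lines recording the
#' mode, seed and random-tree model, and followed by the per-size
#' aggregate block.
#'
#' @param x an `experiment_result`.
#' @param path output file.
#' @export
write_experiment_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mode: %s", x$mode), con)
  writeLines(sprintf("# seed: %d", x$seed), con)
  writeLines(sprintf("# model: %s", x$model), con)
  utils::write.csv(x$trials, con, row.names = FALSE)
  writeLines("# per-size aggregates", con)
  utils::write.csv(x$summary, con, row.names = FALSE)
  invisible(path)
}
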