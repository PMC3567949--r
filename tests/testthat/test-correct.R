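S3 <- function() nwk("((1,2),3);")

test_that("AD-border collects highest NAD-free apparent duplications", {
  s <- S3()
  t <- nwk("((1,1),2);")
  b <- ad_border(t, s)
  expect_length(b, 1)
  expect_setequal(genome_set(t, b), "1")

  expect_length(ad_border(nwk("((1,3),2);"), s), 0)   # uniquely labelled
  # root is AD but holds a NAD below: excluded
  expect_length(ad_border(nwk("(((1,3),2),1);"), s), 0)
})

test_that("NAD-border collects highest AD-free subtrees, leaves included", {
  t <- nwk("((1,3),2);")
  expect_equal(nad_border(t), t$root)
  t2 <- nwk("(((1,3),2),1);")
  b <- nad_border(t2)
  expect_length(b, 2)
  sets <- lapply(b, function(v) genome_set(t2, v))
  expect_true(any(vapply(sets, function(x) setequal(x, c("1", "2", "3")), TRUE)))
  expect_true(any(vapply(sets, function(x) identical(x, "1"), TRUE)))
})

test_that("induced weighted trees take the species shape with occurrence weights", {
  s <- S3()
  w <- induced_weighted_tree(nwk("(1,(1,2));"), s)
  expect_equal(write_newick(w), "(1:2,2:1);")
  expect_equal(sum(w$weight[!is.na(w$label)]), 3)    # v(W) = |U|

  full <- induced_weighted_tree(nwk("(3,(2,1));"), s)
  expect_equal(write_newick(full), "((1:1,2:1),3:1);")
})

test_that("T^I replaces exactly the AD-border subtrees", {
  s <- S3()
  u <- nwk("((1,3),2);")
  ti <- build_ti(u, s)
  expect_true(iso(ti$tree, u))
  expect_equal(ti$orig_uid, u$uid)

  t <- nwk("((1,1),2);")
  ti2 <- build_ti(t, s)
  expect_equal(write_newick(ti2$tree), "(1:2,2:1);")
  # collapsed region root keeps the original AD vertex's identifier
  lf1 <- which(ti2$tree$label == "1")
  expect_equal(ti2$orig_uid[lf1], t$uid[ad_border(t, s)])
})

test_that("Constraint C detects apparent duplications above NADs", {
  s <- S3()
  expect_true(satisfies_constraint_c(nwk("((1,3),2);"), s))    # no AD at all
  expect_false(satisfies_constraint_c(nwk("(((1,3),2),1);"), s))
  expect_true(satisfies_constraint_c(nwk("((1,2),3);"), s))    # MD-consistent
  expect_true(satisfies_constraint_c(nwk("((1,1),2);"), s))
})

test_that("Correct-Tree resolves the worked examples and always yields MD trees", {
  s <- S3()
  expect_equal(correct_tree(nwk("((1,2),3);"), s)$removals, 0)

  rep1 <- correct_tree(nwk("((1,3),2);"), s)
  expect_equal(rep1$removals, 1)
  expect_true(is_md_consistent(rep1$corrected, s))
  expect_equal(tree_size(rep1$corrected), 2)

  rep2 <- correct_tree(nwk("(((1,3),2),1);"), s)
  expect_equal(rep2$removals, 1)
  expect_true(is_md_consistent(rep2$corrected, s))
  expect_equal(nrow(rep2$removed_leaves), 1)
})

test_that("corrected trees are MD-consistent and removals match sizes", {
  set.seed(401)
  for (i in 1:120) {
    sp <- random_species_tree(as.character(1:5))
    t <- random_gene_tree(sample(4:14, 1), as.character(1:5))
    rep <- correct_tree(t, sp)
    expect_true(is_md_consistent(rep$corrected, sp))
    expect_equal(rep$removals, tree_size(t) - tree_size(rep$corrected))
    expect_equal(rep$removals, nrow(rep$removed_leaves))
    # removed leaves are reported by stable identifiers of the input tree
    expect_true(all(rep$removed_leaves$uid %in% t$uid))
  }
})

test_that("Correct-Tree is exact on uniquely leaf-labelled trees (MAST reduction)", {
  set.seed(402)
  for (i in 1:80) {
    t <- random_unique_tree(sample(4:8, 1), as.character(1:8))
    sp <- random_species_tree(genome_set(t))
    n <- correct_tree(t, sp)$removals
    expect_equal(n, tree_size(t) - mast(t, sp)$score)
    expect_equal(n, exact_min_removals(t, sp)$n_opt)
  }
})

test_that("Correct-Tree is exact under Constraint C, removing whole label classes", {
  set.seed(403)
  done <- 0
  while (done < 60) {
    sp <- random_species_tree(as.character(1:5))
    t <- random_gene_tree(sample(4:12, 1), as.character(1:5))
    if (!satisfies_constraint_c(t, sp)) next
    if (is_md_consistent(t, sp)) next
    done <- done + 1
    n <- correct_tree(t, sp)$removals
    opt <- exact_min_removals(t, sp)
    expect_equal(n, opt$n_opt)
    # optimal solutions drop all copies of a species or none
    lv <- which(is.na(t$kids[, 1]))
    copies <- table(t$label[lv])
    dropped <- table(factor(opt$removed$label, levels = names(copies)))
    touched <- names(dropped)[dropped > 0]
    expect_true(all(dropped[touched] == copies[touched]))
  }
})

test_that("the exhaustive oracle lower-bounds the heuristic", {
  set.seed(404)
  for (i in 1:40) {
    sp <- random_species_tree(as.character(1:5))
    t <- random_gene_tree(sample(5:12, 1), as.character(1:5))
    n <- correct_tree(t, sp)$removals
    nopt <- exact_min_removals(t, sp)$n_opt
    expect_lte(nopt, n)
    expect_true(is_md_consistent(exact_min_removals(t, sp)$corrected, sp))
  }
  expect_equal(exact_min_removals(nwk("((1,2),3);"), S3())$n_opt, 0)
  expect_error(exact_min_removals(nwk("((((1,3),2),(3,1)),2);"), S3(), cap = 0),
               "cap")
})

test_that("species removal via MAST on T^I solves the known-species-tree case", {
  s <- S3()
  res <- min_species_removal_correct(nwk("((1,3),2);"), s)
  expect_length(res$removed_species, 1)
  srs <- restrict_to(s, res$kept_species)
  expect_true(is_md_consistent(res$corrected, srs))

  res0 <- min_species_removal_correct(nwk("((1,2),3);"), s)
  expect_length(res0$removed_species, 0)

  expect_error(min_species_removal_correct(nwk("(((1,3),2),1);"), s),
               "AD vertex above")

  # uniquely leaf-labelled: species removal equals leaf removal
  set.seed(405)
  for (i in 1:25) {
    t <- random_unique_tree(sample(4:7, 1), as.character(1:7))
    sp <- random_species_tree(genome_set(t))
    expect_equal(length(min_species_removal_correct(t, sp)$removed_species),
                 correct_tree(t, sp)$removals)
  }
})

test_that("forest correction aggregates per-tree reports", {
  s <- S3()
  f <- list(nwk("((1,3),2);"), nwk("((1,2),3);"))
  rep <- correct_forest(f, s)
  expect_equal(rep$removals, 1)
  expect_equal(rep$removed_leaves$tree, 1)
  expect_true(all(vapply(rep$corrected, is_md_consistent, TRUE, s = s)))
})
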