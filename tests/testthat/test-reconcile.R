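S3 <- function() nwk("((1,2),3);")

test_that("LCA mapping sends each vertex to the LCA of its genome set", {
  s <- S3()
  t <- nwk("((1,3),2);")
  M <- lca_map(t, s)
  inner <- setdiff(which(is.na(t$label)), t$root)
  expect_equal(M[inner], s$root)                 # LCA of {1,3} is the root
  expect_equal(M[t$root], s$root)
  expect_equal(genome_set(s, M[which(t$label == "2")]), "2")

  ch <- nwk("(1,2);")
  expect_setequal(genome_set(s, lca_map(ch, s)[ch$root]), c("1", "2"))
  expect_error(lca_map(nwk("(1,9);"), s), "'9'")
})

test_that("event classification separates speciation, AD and NAD", {
  s <- S3()
  ev <- classify_events(nwk("((1,3),2);"), s)
  expect_equal(sort(ev$events$event), c("NAD", "SPECIATION"))
  expect_equal(ev$dup_count, 1)
  expect_equal(ev$nad_count, 1)
  expect_equal(ev$dup_count, ev$ad_count + ev$nad_count)

  ev2 <- classify_events(nwk("((1,1),2);"), s)
  expect_equal(ev2$ad_count, 1)
  expect_equal(ev2$nad_count, 0)

  ev3 <- classify_events(nwk("((1,2),3);"), s)
  expect_equal(ev3$dup_count, 0)
  expect_true(all(ev3$events$event == "SPECIATION"))
})

test_that("the LCA reconciliation reproduces the worked three-species example", {
  s <- S3()
  for (txt in c("((1,3),2);", "(1,(2,3));")) {
    t <- nwk(txt)
    expect_equal(duplication_cost(t, s), 1)
    expect_equal(loss_cost(t, s), 3)
    expect_equal(mutation_cost(t, s), 4)
    r <- build_reconciliation(t, s)
    expect_equal(r$losses, 3)
    expect_equal(length(r$tree$graft), 3)
    expect_true(is_ds_consistent(r$tree, s))
  }
  expect_equal(mutation_cost(nwk("((1,2),3);"), s), 0)
  r0 <- build_reconciliation(nwk("(1,2);"), s)
  expect_equal(r0$losses, 0)
  expect_equal(r0$dup_count, 0)
})

test_that("DS-consistency accepts the species tree and rejects conflicts", {
  s <- S3()
  expect_true(is_ds_consistent(s, s))
  expect_false(is_ds_consistent(nwk("((1,3),2);"), s))
  expect_true(is_ds_consistent(nwk("((1,1),2);"), nwk("(1,2);")))
})

test_that("MD-consistency holds iff no NAD vertex exists", {
  s <- S3()
  expect_false(is_md_consistent(nwk("((1,3),2);"), s))
  expect_true(is_md_consistent(nwk("((1,1),2);"), s))
  # two-leaf gene trees are MD-consistent with every species tree
  for (sp in all_species_trees(as.character(1:4))) {
    expect_true(is_md_consistent(nwk("(1,2);"), sp))
    expect_true(is_md_consistent(nwk("(3,3);"), sp))
  }
})

test_that("each NAD vertex exhibits a wrong species triplet", {
  s <- S3()
  t <- nwk("((1,3),2);")
  x <- local({ ev <- classify_events(t, s); ev$events$node[ev$events$event == "NAD"] })
  wt <- wrong_triplet(t, s, x)
  expect_equal(wt$triplet, c("1", "2", "3"))
  expect_setequal(wt$gene_split$pair, c("1", "3"))
  expect_setequal(wt$species_split$pair, c("1", "2"))

  t2 <- nwk("(1,(2,3));")
  x2 <- local({ ev <- classify_events(t2, s); ev$events$node[ev$events$event == "NAD"] })
  wt2 <- wrong_triplet(t2, s, x2)
  expect_setequal(wt2$gene_split$pair, c("2", "3"))
  expect_setequal(wt2$species_split$pair, c("1", "2"))

  spec_node <- local({ ev <- classify_events(t, s)
    ev$events$node[ev$events$event == "SPECIATION"] })
  expect_error(wrong_triplet(t, s, spec_node), "not a NAD")
})

test_that("reconciliation invariants hold on random instances", {
  set.seed(201)
  for (i in 1:150) {
    sp <- random_species_tree(as.character(1:5))
    t <- random_gene_tree(sample(3:10, 1), as.character(1:5))
    r <- build_reconciliation(t, sp)
    expect_true(is_ds_consistent(r$tree, sp))
    expect_equal(r$losses, loss_cost(t, sp))
    expect_equal(r$dup_count, duplication_cost(t, sp))
    # duplication vertices of the extension equal d(T,S)
    expect_equal(r$extension_events$dup_count, r$dup_count)
    # every NAD yields a wrong triplet
    ev <- classify_events(t, sp)
    for (x in ev$events$node[ev$events$event == "NAD"]) {
      wt <- wrong_triplet(t, sp, x)
      expect_length(wt$triplet, 3)
      expect_false(setequal(wt$gene_split$pair, wt$species_split$pair))
    }
  }
})

test_that("AD vertices stay duplications under every species tree", {
  set.seed(202)
  trees <- all_species_trees(as.character(1:4))
  found <- 0
  while (found < 10) {
    t <- random_gene_tree(sample(4:7, 1), as.character(1:4))
    ev <- classify_events(t, trees[[1]])
    adn <- ev$events$node[ev$events$event == "AD"]
    if (!length(adn)) next
    found <- found + 1
    for (sp in trees) {
      evs <- classify_events(t, sp)
      expect_true(all(evs$events$event[match(adn, evs$events$node)] == "AD"))
    }
  }
})
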