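test_that("level sets skip apparent duplications without incrementing depth", {
  f1 <- list(nwk("(1,2);"))
  lv1 <- compute_levels(f1)
  expect_length(lv1$levels, 1)
  expect_equal(nrow(lv1$levels[[1]]), 1)

  f2 <- list(nwk("((1,1),2);"))
  lv2 <- compute_levels(f2)
  expect_length(lv2$levels, 1)          # AD cherry contributes nothing below
  expect_equal(lv2$levels[[1]]$node, f2[[1]]$root)

  f3 <- list(nwk("((1,2),3);"), nwk("((1,3),2);"))
  lv3 <- compute_levels(f3)
  expect_length(lv3$levels, 2)
  expect_equal(nrow(lv3$levels[[1]]), 2)    # both roots
  expect_equal(nrow(lv3$levels[[2]]), 2)    # nodes (1,2) and (1,3)
})

test_that("level hypergraphs hold the child genome sets as hyperedges", {
  f1 <- list(nwk("(1,2);"))
  h1 <- build_level_hypergraph(compute_levels(f1)$levels[[1]], f1)
  expect_setequal(h1$vertices, c("1", "2"))
  expect_setequal(vapply(h1$edges, paste, "", collapse = ","), c("1", "2"))

  f3 <- list(nwk("((1,2),3);"), nwk("((1,3),2);"))
  h0 <- build_level_hypergraph(compute_levels(f3)$levels[[1]], f3)
  expect_setequal(vapply(h0$edges, paste, "", collapse = ","),
                  c("1,2", "3", "1,3", "2"))
})

test_that("hypergraph connectivity works on the clique expansion", {
  H <- function(edges) structure(list(vertices = sort(unique(unlist(edges))),
                                      edges = edges),
                                 class = "level_hypergraph")
  expect_false(hypergraph_connected(H(list("1", "2"))))
  expect_true(hypergraph_connected(H(list(c("1", "2"), "3", c("1", "3"), "2"))))
  expect_true(hypergraph_connected(H(list(c("1", "2", "3")))))
})

test_that("minimum vertex cuts match exhaustive search", {
  H <- function(edges) structure(list(vertices = sort(unique(unlist(edges))),
                                      edges = edges),
                                 class = "level_hypergraph")
  # path a-b-c: b is the unique cut vertex
  expect_equal(min_vertex_cut(H(list(c("a", "b"), c("b", "c")))), "b")
  expect_equal(min_vertex_cut(H(list(c("1", "2"), "3", c("1", "3"), "2"))), "1")
  # complete expansion: no cut exists
  expect_null(min_vertex_cut(H(list(c("1", "2", "3")))))

  set.seed(501)
  done <- 0
  while (done < 60) {
    h <- random_hypergraph(sample(4:8, 1), sample(2:6, 1))
    if (length(h$vertices) < 3 || !hypergraph_connected(h)) next
    got <- min_vertex_cut(h)
    want <- brute_min_cut(h)
    if (is.null(want)) { expect_null(got); next }
    done <- done + 1
    expect_length(got, length(want))
    # the returned set is itself a disconnecting set
    expect_false(hypergraph_connected(structure(
      list(vertices = setdiff(h$vertices, got),
           edges = lapply(h$edges, setdiff, y = got)),
      class = "level_hypergraph")))
  }
})

test_that("species-removal inference reaches a certified MD-forest", {
  f1 <- list(nwk("(1,2);"))
  r1 <- minimum_species_removal_inference(f1)
  expect_setequal(r1$kept_species, c("1", "2"))

  f3 <- list(nwk("((1,2),3);"), nwk("((1,3),2);"))
  r3 <- minimum_species_removal_inference(f3)
  expect_length(r3$kept_species, 2)
  expect_false(is.null(r3$species_tree))

  # an MD-forest loses nothing
  fmd <- list(nwk("((1,2),3);"), nwk("((1,1),2);"))
  rmd <- minimum_species_removal_inference(fmd)
  expect_setequal(rmd$kept_species, c("1", "2", "3"))
})

test_that("inference certificates hold on random forests", {
  set.seed(502)
  for (i in 1:25) {
    f <- lapply(seq_len(sample(2:4, 1)), function(j)
      random_gene_tree(sample(3:8, 1), as.character(1:5)))
    res <- minimum_species_removal_inference(f)
    st <- infer_md_species_tree(res$forest, genome_set_hint = res$kept_species)
    expect_false(is.null(st))
    for (t in res$forest) {
      expect_equal(duplication_cost(t, st), sum(gtcorrect:::ad_flags(t)$ad))
    }
  }
})

test_that("the species-tree-known case reduces to inference (forest + S)", {
  s <- nwk("((1,2),3);")
  rmd <- minsrr_via_minsri(list(nwk("((1,2),3);"), nwk("((1,1),2);")), s)
  expect_setequal(rmd$kept_species, c("1", "2", "3"))

  r <- minsrr_via_minsri(list(nwk("((1,3),2);")), s)
  expect_length(r$kept_species, 2)
  expect_true(all(r$kept_species %in% genome_set(s)))
  expect_true(is_md_consistent(r$forest[[1]],
                               restrict_to(s, r$kept_species)))
})

test_that("MD-forest decision builds a certified parsimonious species tree", {
  expect_equal(write_newick(infer_md_species_tree(list(nwk("(1,2);")))), "(1,2);")
  expect_null(infer_md_species_tree(list(nwk("((1,2),3);"), nwk("((1,3),2);"))))

  # a lone species tree certifies itself with zero duplications
  set.seed(503)
  for (i in 1:10) {
    s <- random_species_tree(as.character(1:6))
    st <- infer_md_species_tree(list(s))
    expect_false(is.null(st))
    expect_equal(duplication_cost(s, st), 0)
  }
})

test_that("forests of duplicated-leaf trees are always MD-forests", {
  set.seed(504)
  for (i in 1:25) {
    s <- random_species_tree(as.character(1:6))
    f <- lapply(1:3, function(j) random_md_tree(s, sample(6:12, 1)))
    st <- infer_md_species_tree(f)
    expect_false(is.null(st))
    for (t in f) expect_true(is_md_consistent(t, st))
  }
})
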