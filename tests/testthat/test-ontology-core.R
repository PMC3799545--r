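test_that("closure is reflexive and follows asserted chains", {
  g <- ontology_graph(is_a = edge_df(c("CHEBI:17234", "CHEBI:33917"),
                                     c("CHEBI:33917", "CHEBI:16646")))
  cl <- subclass_closure(g)
  expect_true(is_subclass_of(cl, "CHEBI:17234", "CHEBI:17234"))
  expect_true(is_subclass_of(cl, "CHEBI:17234", "CHEBI:33917"))
  expect_true(is_subclass_of(cl, "CHEBI:17234", "CHEBI:16646"))
  expect_false(is_subclass_of(cl, "CHEBI:16646", "CHEBI:17234"))
  expect_error(is_subclass_of(cl, "CHEBI:17234", "CHEBI:99999"),
               "CHEBI:99999")
})

test_that("closure matches brute-force reachability on random DAGs", {
  set.seed(11)
  ids <- sprintf("N:%03d", 1:200)
  edges <- random_dag(ids, p = 0.02)
  cl <- subclass_closure(ontology_graph(classes = ids, is_a = edges))
  bfs_edges <- data.frame(from = edges$child, to = edges$parent,
                          stringsAsFactors = FALSE)
  for (a in sample(ids, 40)) {
    expect_identical(superclasses_of(cl, a), bfs_reach(bfs_edges, a))
  }
})

test_that("merging disjoint graphs leaves closures unchanged", {
  g1 <- ontology_graph(is_a = edge_df("A:2", "A:1"))
  g2 <- ontology_graph(is_a = edge_df("B:2", "B:1"))
  m <- merge_graphs(list(g1, g2))
  cl <- subclass_closure(m)
  expect_true(is_subclass_of(cl, "A:2", "A:1"))
  expect_false(is_subclass_of(cl, "A:2", "B:1"))
})

test_that("bridging equivalences make subclasses cross ontologies", {
  zfa <- ontology_graph(is_a = edge_df("ZFA:0000108", "ZFA:0000107"))
  uberon <- ontology_graph(is_a = edge_df("UBERON:0000970", "UBERON:0000061"))
  m <- merge_graphs(list(zfa, uberon),
                    equivalences = equiv_df("ZFA:0000107", "UBERON:0000970"))
  cl <- subclass_closure(m)
  expect_true(is_subclass_of(cl, "ZFA:0000108", "UBERON:0000061"))
  expect_true(is_subclass_of(cl, "ZFA:0000107", "UBERON:0000970"))
  expect_true(is_subclass_of(cl, "UBERON:0000970", "ZFA:0000107"))
})

test_that("equivalences referencing unknown classes are skipped with warning", {
  g <- ontology_graph(classes = c("A:1", "B:1"))
  expect_warning(m <- merge_graphs(list(g), equivalences = equiv_df("A:1", "C:9")),
                 "skipping")
  expect_equal(nrow(m$equivalences), 0L)
  expect_equal(nrow(attr(m, "skipped_equivalences")), 1L)
})

test_that("random contractions match the brute-force oracle", {
  set.seed(12)
  for (i in 1:25) {
    w <- random_world(nq = 4, ne = 5)
    g <- world_graph(w)
    cl <- subclass_closure(g)
    all_ids <- g$classes
    for (k in 1:20) {
      a <- sample(all_ids, 1); b <- sample(all_ids, 1)
      expect_equal(is_subclass_of(cl, a, b),
                   oracle_is_subclass(w$is_a, w$equiv, a, b),
                   info = paste(i, a, b))
    }
  }
})

test_that("mutual subsumption holds exactly within equivalence groups", {
  set.seed(13)
  w <- random_world(nq = 3, ne = 6)
  g <- world_graph(w)
  cl <- subclass_closure(g)
  for (a in g$classes) for (b in g$classes) {
    both <- is_subclass_of(cl, a, b) && is_subclass_of(cl, b, a)
    expect_equal(both, cl$rep_of[[a]] == cl$rep_of[[b]])
  }
})

test_that("part_of reachability is only visible in the liberal entity mode", {
  g <- ontology_graph(classes = c("E:1", "E:2"),
                      part_of = data.frame(part = "E:2", whole = "E:1"))
  cl <- subclass_closure(g)
  expect_false(is_subclass_of(cl, "E:2", "E:1"))
  expect_true(is_subclass_of(cl, "E:2", "E:1", mode = "is_a_plus_part_of"))
})

test_that("monotonicity: adding an is_a edge never removes closure pairs", {
  set.seed(14)
  ids <- sprintf("N:%02d", 1:12)
  e1 <- random_dag(ids, 0.15)
  cl1 <- subclass_closure(ontology_graph(classes = ids, is_a = e1))
  e2 <- rbind(e1, edge_df(ids[10], ids[3]))
  cl2 <- subclass_closure(ontology_graph(classes = ids, is_a = e2))
  for (a in ids) expect_true(all(superclasses_of(cl1, a) %in%
                                   superclasses_of(cl2, a)))
})

test_that("is_a cycles among non-equivalent classes abort the build", {
  g <- ontology_graph(is_a = edge_df(c("A:1", "A:2"), c("A:2", "A:1")))
  expect_error(subclass_closure(g), "cycle")
  # the same two-way reachability via an asserted equivalence is fine
  g2 <- ontology_graph(classes = c("A:1", "A:2"),
                       is_a = edge_df("A:1", "A:2"),
                       equivalences = equiv_df("A:1", "A:2"))
  expect_silent(subclass_closure(g2))
})
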