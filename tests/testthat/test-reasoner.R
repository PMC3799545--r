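glucose_world <- function(with_edge = TRUE) {
  is_a <- edge_df(c("PATO:0001163", if (with_edge) "CHEBI:17234"),
                  c("PATO:0000033", if (with_edge) "CHEBI:33917"))
  ontology_graph(classes = c("PATO:0000033", "PATO:0001163", "PATO:0000460",
                             "CHEBI:17234", "CHEBI:33917", "FMA:9670"),
                 is_a = is_a)
}

hypo_def <- eq_definition("HP:0001943", quality = "PATO:0001163",
                          bearer = "FMA:9670", towards = "CHEBI:17234",
                          qualifier = "PATO:0000460")
dec_aldo_def <- eq_definition("HP:0040001", quality = "PATO:0001163",
                              bearer = "FMA:9670", towards = "CHEBI:33917",
                              qualifier = "PATO:0000460")

test_that("the glucose-aldohexose edge drives the hypoglycemia inference", {
  cl <- subclass_closure(glucose_world(TRUE))
  expect_true(eq_subsumes(hypo_def, dec_aldo_def, cl))
  expect_false(eq_subsumes(dec_aldo_def, hypo_def, cl))
  # without the chemical subclass edge the inference disappears
  cl0 <- subclass_closure(glucose_world(FALSE))
  expect_false(eq_subsumes(hypo_def, dec_aldo_def, cl0))
  # reflexivity
  expect_true(eq_subsumes(hypo_def, hypo_def, cl))
})

test_that("an absent bearer in the subsumer counts as entailed", {
  cl <- subclass_closure(glucose_world(TRUE))
  quality_only <- eq_definition("HP:0000001", quality = "PATO:0000033",
                                qualifier = "PATO:0000460")
  expect_true(eq_subsumes(hypo_def, quality_only, cl))
  expect_false(eq_subsumes(quality_only, hypo_def, cl))
})

test_that("definitions over unknown classes entail only themselves and are reported", {
  cl <- with_unknown_report(subclass_closure(glucose_world(TRUE)))
  mystery <- eq_definition("MP:0000009", quality = "PATO:9999999",
                           qualifier = "PATO:0000460")
  expect_true(eq_subsumes(mystery, mystery, cl))
  expect_false(eq_subsumes(mystery, dec_aldo_def, cl))
  expect_equal(unknown_classes(cl), "PATO:9999999")
})

test_that("pairwise subsumption agrees with the brute-force oracle", {
  set.seed(51)
  for (i in 1:40) {
    w <- random_world()
    g <- world_graph(w)
    cl <- subclass_closure(g)
    defs <- random_defs(w, sprintf("HP:%07d", 1:4))
    for (mode in c("is_a_only", "is_a_plus_part_of")) {
      for (a in names(defs)) for (b in names(defs)) {
        expect_equal(
          eq_subsumes(defs[[a]], defs[[b]], cl, mode),
          oracle_eq_subsumes(defs[[a]], defs[[b]], w$is_a, w$part_of,
                             w$equiv, mode),
          info = paste(i, mode, a, b))
      }
    }
  }
})

test_that("classification equals the exhaustive oracle on small fixtures", {
  set.seed(52)
  for (i in 1:30) {
    w <- random_world()
    g <- world_graph(w)
    cl <- subclass_closure(g)
    nd <- sample(2:5, 1)
    ids <- sprintf("HP:%07d", seq_len(nd))
    defs <- random_defs(w, ids)
    und <- sprintf("MP:%07d", 1:2)
    asserted <- edge_df(c(ids[1], und[2]), c(und[1], und[1]))
    eqp <- if (stats::runif(1) < 0.5) equiv_df(ids[1], und[2]) else equiv_df()
    res <- classify(defs, asserted_is_a = asserted, closure = cl,
                    asserted_equivalences = eqp, classes = und)
    oracle <- oracle_classify(defs, asserted, eqp, w$is_a, w$part_of,
                              w$equiv, und)
    expect_identical(res$matrix, oracle$matrix)
    expect_identical(unname(res$equivalence_groups), unname(oracle$groups))
  }
})

test_that("classify output is transitively closed and reflexive", {
  set.seed(53)
  w <- random_world()
  cl <- subclass_closure(world_graph(w))
  defs <- random_defs(w, sprintf("HP:%07d", 1:6))
  res <- classify(defs, closure = cl)
  M <- res$matrix
  expect_true(all(diag(M)))
  expect_identical(M, xspheno:::transitive_close(M))
})

test_that("identical definitions in two namespaces form one equivalence group", {
  w <- random_world(nq = 3, ne = 3)
  cl <- subclass_closure(world_graph(w))
  mk <- function(id) eq_definition(id, quality = "Q:001", bearer = "E:001",
                                   qualifier = "PATO:0000460")
  res <- classify(list(`HP:0005609` = mk("HP:0005609"),
                       `ZP:0004170` = mk("ZP:0004170")), closure = cl)
  expect_equal(res$equivalence_groups[[1]], c("HP:0005609", "ZP:0004170"))
})

test_that("incomparable qualities leave only reflexive and asserted pairs", {
  g <- ontology_graph(classes = c("Q:001", "Q:002", "E:001", "PATO:0000460"))
  cl <- subclass_closure(g)
  defs <- list(
    `HP:0000001` = eq_definition("HP:0000001", "Q:001", "E:001",
                                 qualifier = "PATO:0000460"),
    `HP:0000002` = eq_definition("HP:0000002", "Q:002", "E:001",
                                 qualifier = "PATO:0000460"))
  res <- classify(defs, closure = cl)
  expect_equal(nrow(res$subclass_pairs), 2L)
  expect_true(all(res$subclass_pairs$sub == res$subclass_pairs$super))
})

test_that("the liberal entity mode yields a superset of subclass pairs", {
  set.seed(54)
  for (i in 1:10) {
    w <- random_world()
    cl <- subclass_closure(world_graph(w))
    defs <- random_defs(w, sprintf("HP:%07d", 1:5))
    conservative <- classify(defs, closure = cl, entity_mode = "is_a_only")
    liberal <- classify(defs, closure = cl, entity_mode = "is_a_plus_part_of")
    key <- function(r) paste(r$subclass_pairs$sub, r$subclass_pairs$super)
    expect_true(all(key(conservative) %in% key(liberal)))
  }
})

test_that("process definitions induce genus and pairwise hierarchy edges", {
  g <- ontology_graph(classes = c("GO:0043473", "GO:0048069",
                                  "UBERON:0000970", "UBERON:0000061"),
                      is_a = edge_df("UBERON:0000970", "UBERON:0000061"))
  cl <- subclass_closure(g)
  defs <- list(
    `GO:0048069` = eq_definition("GO:0048069", quality = "GO:0043473",
                                 bearer = "UBERON:0000970"))
  e <- infer_process_hierarchy(defs, cl)
  expect_equal(e, edge_df("GO:0048069", "GO:0043473"))
})
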