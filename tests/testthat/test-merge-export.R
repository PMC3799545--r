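# classification results built directly from a small world, reused below
merge_fixture <- function(seed = 61, nd = 6) {
  set.seed(seed)
  w <- random_world()
  cl <- subclass_closure(world_graph(w))
  ids <- c(sprintf("HP:%07d", seq_len(nd)), sprintf("MP:%07d", seq_len(nd)),
           sprintf("ZP:%07d", seq_len(nd)))
  defs <- random_defs(w, ids)
  res <- classify(defs, closure = cl)
  labels <- stats::setNames(paste("pheno", seq_along(ids)), ids)
  list(res = res, labels = labels)
}

test_that("HP members always win primary selection; MP outranks ZP", {
  mk_result <- function(groups) {
    ids <- sort(unlist(groups))
    M <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
    diag(M) <- TRUE
    for (g in groups) for (a in g) for (b in g) M[a, b] <- TRUE
    structure(list(classes = ids, equivalence_groups = lapply(groups, sort),
                   matrix = M,
                   subclass_pairs = NULL),
              class = "subsumption_result")
  }
  m <- merge_clusters(mk_result(list(c("ZP:0004170", "HP:0005609"))))
  expect_equal(m$clusters[[1]]$primary_id, "HP:0005609")
  expect_equal(m$clusters[[1]]$alt_ids, "ZP:0004170")
  m2 <- merge_clusters(mk_result(list(c("ZP:0000001", "MP:0000002"))))
  expect_equal(m2$clusters[[1]]$primary_id, "MP:0000002")
  # lexicographic tie-break within a prefix
  m3 <- merge_clusters(mk_result(list(c("HP:0000009", "HP:0000002"))))
  expect_equal(m3$clusters[[1]]$primary_id, "HP:0000002")
})

test_that("all-singleton groups reproduce the transitive reduction of the input", {
  ids <- c("HP:0000001", "HP:0000002", "HP:0000003")
  M <- matrix(FALSE, 3, 3, dimnames = list(ids, ids))
  diag(M) <- TRUE
  M[1, 2] <- M[2, 3] <- M[1, 3] <- TRUE     # chain with its implied edge
  res <- structure(list(classes = ids, matrix = M,
                        equivalence_groups = as.list(ids)),
                   class = "subsumption_result")
  m <- merge_clusters(res)
  expect_length(m$clusters, 3L)
  expect_equal(m$dag, edge_df(c("HP:0000001", "HP:0000002"),
                              c("HP:0000002", "HP:0000003")))
})

test_that("every phenotype id appears exactly once in the export", {
  fx <- merge_fixture()
  m <- merge_clusters(fx$res, fx$labels)
  doc <- export_cross_species(m)
  seen <- unlist(lapply(doc$stanzas, function(s) c(s$id, s$alt_ids)))
  seen <- setdiff(seen, "CP:0000001")
  expect_identical(sort(seen), sort(fx$res$classes))
  expect_equal(anyDuplicated(seen), 0L)
})

test_that("closing the exported is_a edges reproduces the reasoner subsumption", {
  for (seed in 61:64) {
    fx <- merge_fixture(seed)
    m <- merge_clusters(fx$res, fx$labels)
    doc <- export_cross_species(m)
    edges <- do.call(rbind, lapply(doc$stanzas, function(s)
      if (length(s$is_a)) data.frame(from = s$id, to = s$is_a)))
    for (a in fx$res$classes) for (b in fx$res$classes) {
      pa <- m$primary_of[[a]]; pb <- m$primary_of[[b]]
      expect_equal(pb %in% bfs_reach(edges, pa), fx$res$matrix[a, b],
                   info = paste(seed, a, b))
    }
  }
})

test_that("transitive reduction never loses or adds closure content", {
  for (seed in 65:68) {
    fx <- merge_fixture(seed)
    m <- merge_clusters(fx$res, fx$labels)
    # closure of the reduced DAG on primaries == strict primary closure
    prim <- vapply(m$clusters, `[[`, character(1), "primary_id")
    edges <- data.frame(from = m$dag$child, to = m$dag$parent)
    for (p in prim) {
      reach <- setdiff(bfs_reach(edges, p), p)
      direct <- unique(unname(m$primary_of[
        fx$res$classes[fx$res$matrix[names(which(m$primary_of == p))[1], ]]]))
      expect_setequal(reach, setdiff(direct, p))
    }
    # no reduced edge is implied by two others
    for (i in seq_len(nrow(m$dag))) {
      u <- m$dag$child[i]; v <- m$dag$parent[i]
      others <- m$dag[-i, , drop = FALSE]
      expect_false(v %in% bfs_reach(data.frame(from = others$child,
                                               to = others$parent), u),
                   info = paste(seed, u, v))
    }
  }
})

test_that("shuffled classification input yields byte-identical OBO output", {
  set.seed(71)
  w <- random_world()
  cl <- subclass_closure(world_graph(w))
  ids <- c(sprintf("HP:%07d", 1:4), sprintf("MP:%07d", 1:4))
  defs <- random_defs(w, ids)
  labels <- stats::setNames(paste("pheno", seq_along(ids)), ids)
  out <- lapply(1:3, function(k) {
    sh <- sample(defs)
    res <- classify(sh, closure = cl, classes = sample(ids))
    write_obo(export_cross_species(merge_clusters(res, labels)))
  })
  expect_identical(out[[1]], out[[2]])
  expect_identical(out[[1]], out[[3]])
})

test_that("exports contain no building-block classes and a rooted DAG", {
  fx <- merge_fixture(72)
  doc <- export_cross_species(merge_clusters(fx$res, fx$labels))
  prefixes <- unique(sub(":.*", "", vapply(doc$stanzas, `[[`, character(1), "id")))
  expect_true(all(prefixes %in% c("HP", "MP", "ZP", "CP")))
  # every non-root stanza has a parent
  for (s in doc$stanzas)
    if (s$id != "CP:0000001") expect_gte(length(s$is_a), 1L)
  # empty cluster list: header-only document
  empty <- structure(list(classes = character(),
                          matrix = matrix(FALSE, 0, 0),
                          equivalence_groups = list()),
                     class = "subsumption_result")
  doc0 <- export_cross_species(merge_clusters(empty))
  expect_length(doc0$stanzas, 0L)
})

test_that("a DAG edge touching a non-primary id is a hard error", {
  fx <- merge_fixture(73)
  m <- merge_clusters(fx$res, fx$labels)
  m$dag <- rbind(m$dag, edge_df("HP:9999999", m$clusters[[1]]$primary_id))
  expect_error(export_cross_species(m), "non-primary")
})
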