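# Independent brute-force oracles and random-input generators. These
# deliberately re-derive every result from first principles (BFS
# reachability, exhaustive condition enumeration, Floyd-Warshall closure)
# and never call the package's closure/reasoner internals.

# reflexive reachability by BFS over an edge list (data frame from, to)
bfs_reach <- function(edges, from) {
  seen <- from
  repeat {
    nxt <- setdiff(edges$to[edges$from %in% seen], seen)
    if (!length(nxt)) break
    seen <- c(seen, nxt)
  }
  sort(unique(seen))
}

# oracle subclass test on a graph with equivalences: equivalence pairs act
# as bidirectional edges, so reachability in the augmented graph equals
# reachability after contraction
oracle_is_subclass <- function(is_a, equiv, a, b) {
  edges <- data.frame(from = c(is_a$child, equiv$left, equiv$right),
                      to = c(is_a$parent, equiv$right, equiv$left),
                      stringsAsFactors = FALSE)
  b %in% bfs_reach(edges, a)
}

# oracle for structural EQ subsumption: enumerates the entailment
# conditions directly over BFS reachability
oracle_eq_subsumes <- function(a, b, is_a, part_of, equiv,
                               entity_mode = "is_a_only") {
  ent <- function(x, y, mode) {
    ed <- data.frame(from = c(is_a$child, equiv$left, equiv$right),
                     to = c(is_a$parent, equiv$right, equiv$left),
                     stringsAsFactors = FALSE)
    if (mode == "is_a_plus_part_of")
      ed <- rbind(ed, data.frame(from = part_of$part, to = part_of$whole))
    y %in% bfs_reach(ed, x)
  }
  opt <- function(x, y, mode) {
    if (is.na(y)) TRUE else if (is.na(x)) FALSE else ent(x, y, mode)
  }
  if (!ent(a$quality, b$quality, "is_a_only")) return(FALSE)
  if (!opt(a$bearer, b$bearer, entity_mode)) return(FALSE)
  if (!opt(a$towards, b$towards, "is_a_only")) return(FALSE)
  if (!opt(a$qualifier, b$qualifier, "is_a_only")) return(FALSE)
  for (i in seq_len(nrow(b$extra_entities))) {
    rel <- b$extra_entities$relation[i]
    tgt <- b$extra_entities$target[i]
    mode <- if (rel == "inheres_in") entity_mode else "is_a_only"
    cand <- a$extra_entities$target[a$extra_entities$relation == rel]
    if (!any(vapply(cand, ent, logical(1), y = tgt, mode = mode)))
      return(FALSE)
  }
  TRUE
}

# oracle classification: pairwise oracle subsumption + asserted edges and
# equivalences + Floyd-Warshall transitive closure; SCCs by mutual
# reachability
oracle_classify <- function(defs, asserted, equiv_pheno, is_a, part_of,
                            equiv_bb, classes, entity_mode = "is_a_only") {
  ids <- sort(unique(c(names(defs), asserted$child, asserted$parent,
                       equiv_pheno$left, equiv_pheno$right, classes)))
  n <- length(ids)
  M <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  diag(M) <- TRUE
  for (a in names(defs)) for (b in names(defs)) if (a != b)
    M[a, b] <- oracle_eq_subsumes(defs[[a]], defs[[b]], is_a, part_of,
                                  equiv_bb, entity_mode)
  for (i in seq_len(nrow(asserted)))
    M[asserted$child[i], asserted$parent[i]] <- TRUE
  for (i in seq_len(nrow(equiv_pheno))) {
    M[equiv_pheno$left[i], equiv_pheno$right[i]] <- TRUE
    M[equiv_pheno$right[i], equiv_pheno$left[i]] <- TRUE
  }
  for (k in seq_len(n)) for (i in seq_len(n)) if (M[i, k])
    M[i, ] <- M[i, ] | M[k, ]
  groups <- list()
  for (i in seq_len(n)) {
    members <- ids[M[i, ] & M[, i]]
    groups[[members[1]]] <- sort(members)
  }
  list(matrix = M, groups = groups[order(names(groups))])
}

edge_df <- function(child = character(), parent = character())
  data.frame(child = child, parent = parent, stringsAsFactors = FALSE)

equiv_df <- function(left = character(), right = character())
  data.frame(left = left, right = right, stringsAsFactors = FALSE)

# random DAG over given ids: edges only from later to earlier ids
random_dag <- function(ids, p = 0.2) {
  ch <- character(); pa <- character()
  n <- length(ids)
  if (n >= 2) for (i in 2:n) for (j in 1:(i - 1)) if (stats::runif(1) < p) {
    ch <- c(ch, ids[i]); pa <- c(pa, ids[j])
  }
  edge_df(ch, pa)
}

# random building-block world: a quality DAG, an entity DAG with optional
# part_of edges, and a few cross-graph equivalences
random_world <- function(nq = 5, ne = 5, p = 0.3) {
  qs <- sprintf("Q:%03d", seq_len(nq))
  es <- sprintf("E:%03d", seq_len(ne))
  es2 <- sprintf("F:%03d", seq_len(ne))
  is_a <- rbind(random_dag(qs, p), random_dag(es, p), random_dag(es2, p))
  part_of <- data.frame(part = character(), whole = character(),
                        stringsAsFactors = FALSE)
  if (ne >= 2) for (i in 2:ne) if (stats::runif(1) < 0.3)
    part_of[nrow(part_of) + 1L, ] <- list(es[i], es[sample(i - 1, 1)])
  k <- sample(0:min(2, ne), 1)
  eq <- if (k > 0) {
    idx <- sample(ne, k)
    equiv_df(es[idx], es2[idx])
  } else equiv_df()
  list(qualities = qs, entities = c(es, es2), is_a = is_a,
       part_of = part_of, equiv = eq)
}

random_defs <- function(world, ids) {
  defs <- list()
  for (id in ids) {
    extra <- if (stats::runif(1) < 0.2)
      data.frame(relation = "has_part_quality",
                 target = sample(world$qualities, 1),
                 stringsAsFactors = FALSE)
    else data.frame(relation = character(), target = character(),
                    stringsAsFactors = FALSE)
    defs[[id]] <- eq_definition(
      id,
      quality = sample(world$qualities, 1),
      bearer = if (stats::runif(1) < 0.8) sample(world$entities, 1) else NA,
      towards = if (stats::runif(1) < 0.3) sample(world$qualities, 1) else NA,
      qualifier = "PATO:0000460",
      extra_entities = extra)
  }
  defs
}

world_graph <- function(world) {
  ontology_graph(classes = c(world$qualities, world$entities, "PATO:0000460"),
                 is_a = world$is_a,
                 part_of = world$part_of,
                 equivalences = world$equiv)
}

# random OBO document for round-trip tests
random_obo_doc <- function(n_terms = 6) {
  ids <- sprintf("%s:%07d", sample(c("HP", "MP", "ZP", "XX"), n_terms, TRUE),
                 sample(1e6, n_terms))
  ids <- unique(ids)
  stanzas <- lapply(seq_along(ids), function(i) {
    io <- NULL
    if (stats::runif(1) < 0.4) {
      io <- data.frame(relation = NA_character_,
                       target = sprintf("PATO:%07d", sample(1e5, 1)),
                       stringsAsFactors = FALSE)
      for (rel in sample(c("inheres_in", "towards", "qualifier"),
                         sample(0:3, 1)))
        io[nrow(io) + 1L, ] <- list(rel, sprintf("ZFA:%07d", sample(1e5, 1)))
    }
    rel <- if (stats::runif(1) < 0.3)
      data.frame(relation = "part_of",
                 target = sprintf("UBERON:%07d", sample(1e5, 1)),
                 stringsAsFactors = FALSE)
    else NULL
    obo_stanza(
      ids[i],
      name = paste("term", sample(1e4, 1)),
      is_a = if (i > 1 && stats::runif(1) < 0.5)
        sample(ids[seq_len(i - 1)], 1) else character(),
      relationships = if (is.null(rel)) empty_rel_df() else rel,
      alt_ids = if (stats::runif(1) < 0.3)
        sprintf("ZP:%07d", sample(1e5, sample(1:2, 1))) else character(),
      xrefs = if (stats::runif(1) < 0.3)
        sprintf("FMA:%05d", sample(1e4, 1)) else character(),
      subsets = if (stats::runif(1) < 0.2) "upper_level" else character(),
      intersection_of = io,
      other = if (stats::runif(1) < 0.3)
        paste0("comment: random note ", sample(1e4, 1)) else character())
  })
  obo_document(stanzas, header = c("format-version" = "1.2",
                                   ontology = "toy"))
}

empty_rel_df <- function() data.frame(relation = character(),
                                      target = character(),
                                      stringsAsFactors = FALSE)

# shared small fixture pipeline run, cached per test session
fig_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- tempfile("figfx")
      fx <- generate_fixture(fixture_spec(seed = 101), d)
      cache <<- list(fx = fx, res = run_pipeline(fx$config))
    }
    cache
  }
})
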