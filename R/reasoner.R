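# Structural subsumption over the EQ fragment.
#
# Because every phenotype class is an existential ("has_part some")
# intersection of a quality, a bearer, an optional towards filler and the
# abnormal qualifier, pairwise subsumption decomposes componentwise:
# A is subsumed by B iff every conjunct of B is entailed by a conjunct of A
# under the merged building-block closure. classify() runs the pairwise
# test over all definitions (pruned by quality ancestry), unions asserted
# is_a edges and asserted equivalences, and transitively closes.

#' Structural subsumption between two EQ definitions
#'
#' `a` is subsumed by `b` iff quality(a) is a subclass of quality(b); the
#' bearer of `b` is absent, or the bearer of `a` is present and a subclass
#' of the bearer of `b` under `entity_mode`; the `towards` filler of `b` is
#' absent or entailed by that of `a`; the qualifier of `b` is absent or
#' entailed; and every extra differentia of `b` is entailed by some extra
#' differentia of `a` under the same relation. All subclass tests run over
#' the merged closure. A CURIE absent from the closure entails only itself
#' (reflexivity); each such CURIE is recorded once in the closure's
#' `unknown` report.
#'
#' @param a,b [eq_definition()] objects (normalized).
#' @param closure A [subclass_closure()] over the merged building blocks.
#' @param entity_mode `"is_a_only"` or `"is_a_plus_part_of"`; applies to
#'   bearer (and `inheres_in` extra) entailment only.
#' @return Logical scalar.
#' @export
eq_subsumes <- function(a, b, closure,
                        entity_mode = c("is_a_only", "is_a_plus_part_of")) {
  entity_mode <- match.arg(entity_mode)
  stopifnot(inherits(a, "eq_definition"), inherits(b, "eq_definition"))
  sub <- function(x, y, mode) closure_entails(closure, x, y, mode)
  opt <- function(x, y, mode) {          # y absent => entailed
    if (is.na(y)) return(TRUE)
    if (is.na(x)) return(FALSE)
    sub(x, y, mode)
  }
  if (!sub(a$quality, b$quality, "is_a_only")) return(FALSE)
  if (!opt(a$bearer, b$bearer, entity_mode)) return(FALSE)
  if (!opt(a$towards, b$towards, "is_a_only")) return(FALSE)
  if (!opt(a$qualifier, b$qualifier, "is_a_only")) return(FALSE)
  exb <- b$extra_entities
  if (nrow(exb)) {
    exa <- a$extra_entities
    for (i in seq_len(nrow(exb))) {
      rel <- exb$relation[i]
      mode <- if (rel == "inheres_in") entity_mode else "is_a_only"
      cand <- exa$target[exa$relation == rel]
      if (!any(vapply(cand, sub, logical(1), y = exb$target[i], mode = mode)))
        return(FALSE)
    }
  }
  TRUE
}

# Subclass test tolerant of CURIEs missing from the closure: an unknown
# class entails only itself, and is noted once per closure object.
closure_entails <- function(closure, x, y, mode) {
  known_x <- x %in% closure$classes
  known_y <- y %in% closure$classes
  if (!known_x || !known_y) {
    note_unknown(closure, c(x, y)[!c(known_x, known_y)])
    return(x == y)
  }
  is_subclass_of(closure, x, y, mode)
}

note_unknown <- function(closure, ids) {
  env <- attr(closure, "unknown_env")
  if (is.null(env)) return(invisible())
  env$seen <- union(env$seen, ids)
  invisible()
}

#' Attach a report collector for unknown CURIEs
#'
#' @param closure A [subclass_closure()].
#' @return The closure, with an environment in attribute `unknown_env`
#'   whose `seen` field accumulates each unknown CURIE once.
#' @export
with_unknown_report <- function(closure) {
  e <- new.env(parent = emptyenv())
  e$seen <- character()
  attr(closure, "unknown_env") <- e
  closure
}

#' Unknown CURIEs reported during reasoning
#'
#' @param closure A closure previously passed through
#'   [with_unknown_report()].
#' @return Character vector (possibly empty).
#' @export
unknown_classes <- function(closure) {
  env <- attr(closure, "unknown_env")
  if (is.null(env)) character() else sort(env$seen)
}

#' Classify phenotype classes
#'
#' Computes the full subsumption relation over phenotype classes: pairwise
#' structural subsumption between all definitions (pruned by quality
#' ancestry), unioned with asserted is_a edges within each phenotype
#' ontology (through which undefined classes participate) and asserted
#' equivalence axioms in both directions, then transitively closed.
#' Equivalence groups are the strongly connected components of the result.
#'
#' @param defs Named list of normalized [eq_definition()] objects (each
#'   defined class has exactly one definition).
#' @param asserted_is_a Data frame `child`, `parent` of asserted subclass
#'   edges among phenotype classes.
#' @param closure A [subclass_closure()] over the merged building blocks.
#' @param asserted_equivalences Data frame `left`, `right` of asserted
#'   phenotype-class equivalences (e.g. lexical HP-MP alignments).
#' @param entity_mode Passed to [eq_subsumes()].
#' @param classes Optional extra class CURIEs to include (undefined classes
#'   with no asserted edges).
#' @return An object of class `subsumption_result`: list with `classes`,
#'   `subclass_pairs` (data frame `sub`, `super`, reflexive and transitive)
#'   and `equivalence_groups` (list of character vectors).
#' @export
classify <- function(defs, asserted_is_a = NULL, closure,
                     asserted_equivalences = NULL,
                     entity_mode = c("is_a_only", "is_a_plus_part_of"),
                     classes = character()) {
  entity_mode <- match.arg(entity_mode)
  ids <- sort(unique(c(names(defs), asserted_is_a$child, asserted_is_a$parent,
                       asserted_equivalences$left, asserted_equivalences$right,
                       classes)))
  n <- length(ids)
  M <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  diag(M) <- TRUE

  # pairwise structural subsumption, pruned by quality ancestry
  dn <- names(defs)
  if (length(dn)) {
    quals <- vapply(defs, `[[`, character(1), "quality")
    qanc <- lapply(unique(quals), function(q) {
      if (q %in% closure$classes) superclasses_of(closure, q, "is_a_only") else q
    })
    names(qanc) <- unique(quals)
    for (ai in dn) {
      cand <- dn[quals %in% qanc[[quals[[ai]]]]]
      for (bi in cand) {
        if (ai == bi) next
        if (eq_subsumes(defs[[ai]], defs[[bi]], closure, entity_mode))
          M[ai, bi] <- TRUE
      }
    }
  }
  if (!is.null(asserted_is_a) && nrow(asserted_is_a))
    M[cbind(asserted_is_a$child, asserted_is_a$parent)] <- TRUE
  if (!is.null(asserted_equivalences) && nrow(asserted_equivalences)) {
    M[cbind(asserted_equivalences$left, asserted_equivalences$right)] <- TRUE
    M[cbind(asserted_equivalences$right, asserted_equivalences$left)] <- TRUE
  }
  M <- transitive_close(M)

  groups <- mutual_groups(M)
  idx <- which(M, arr.ind = TRUE)
  pairs <- data.frame(sub = ids[idx[, 1]], super = ids[idx[, 2]],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$sub, pairs$super), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(classes = ids, subclass_pairs = pairs,
                 equivalence_groups = groups, matrix = M),
            class = "subsumption_result")
}

transitive_close <- function(M) {
  repeat {
    M2 <- M | ((M %*% M) > 0)
    if (identical(M2, M)) return(M)
    M <- M2
  }
}

# On a transitively closed reflexive relation, mutual reachability is an
# equivalence relation; groups keyed by their lexicographically smallest
# member.
mutual_groups <- function(M) {
  ids <- rownames(M)
  mut <- M & t(M)
  key <- apply(mut, 1, function(r) ids[r][1])
  grp <- split(ids, key)
  grp <- lapply(grp, sort)
  grp[order(names(grp))]
}

#' @export
print.subsumption_result <- function(x, ...) {
  nontriv <- sum(lengths(x$equivalence_groups) > 1L)
  cat("subsumption result:", length(x$classes), "phenotype classes,",
      nrow(x$subclass_pairs), "subclass pairs,",
      nontriv, "non-singleton equivalence group(s)\n")
  invisible(x)
}

#' Inferred process-hierarchy edges from logical definitions
#'
#' Logical definitions of biological-process classes (the GO cross-product
#' file) are direct equivalences, not phenotype-style `has_part` wrappers:
#' a defined class is therefore subsumed by its genus, and pairwise
#' structural subsumption between two defined processes also holds. The
#' returned edges can be added to the building-block graph before phenotype
#' classification so that process bearers cross species through anatomy.
#'
#' @param defs Named list of normalized [eq_definition()] objects for
#'   process classes.
#' @param closure A [subclass_closure()] over the building blocks.
#' @param entity_mode Passed to [eq_subsumes()].
#' @return Data frame `child`, `parent` of inferred is_a edges.
#' @export
infer_process_hierarchy <- function(defs, closure,
                                    entity_mode = c("is_a_only", "is_a_plus_part_of")) {
  entity_mode <- match.arg(entity_mode)
  edges <- empty_edges("child", "parent")
  for (d in defs)
    edges[nrow(edges) + 1L, ] <- list(d$defined_class, d$quality)
  dn <- names(defs)
  for (ai in dn) for (bi in dn) {
    if (ai != bi && eq_subsumes(defs[[ai]], defs[[bi]], closure, entity_mode))
      edges[nrow(edges) + 1L, ] <- list(ai, bi)
  }
  canon_edges(edges, "child", "parent")
}
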