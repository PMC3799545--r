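# In-memory multi-ontology graph and its reflexive-transitive subclass
# closure. Asserted equivalences (bridging axioms) are contracted before
# reachability so that equivalent classes are mutually substitutable.
#
# part_of edges are stored but NOT folded into subclass closure by default:
# the "is_a_plus_part_of" entity mode exposes the liberal reading
# (is_a + part_of reachability) for bearer-entity subsumption only.

#' Create an ontology graph
#'
#' @param classes Character vector of class CURIEs.
#' @param labels Named character vector mapping CURIEs to labels (may cover
#'   a subset of `classes`).
#' @param is_a Data frame with columns `child`, `parent`.
#' @param part_of Data frame with columns `part`, `whole`.
#' @param subsets Named list mapping CURIE to character vector of subset
#'   names.
#' @param xrefs Named list mapping CURIE to character vector of
#'   cross-referenced CURIEs.
#' @param equivalences Data frame with columns `left`, `right` (and
#'   optionally `provenance`): unordered class pairs treated as identical.
#' @param synonyms Named list mapping CURIE to character vector of exact
#'   synonyms.
#' @return An object of class `ontology_graph`.
#' @export
ontology_graph <- function(classes = character(), labels = character(),
                           is_a = empty_edges("child", "parent"),
                           part_of = empty_edges("part", "whole"),
                           subsets = list(), xrefs = list(),
                           equivalences = empty_equiv(), synonyms = list()) {
  classes <- sort(unique(c(classes, is_a$child, is_a$parent,
                           part_of$part, part_of$whole)))
  structure(list(classes = classes,
                 labels = labels,
                 is_a = canon_edges(is_a, "child", "parent"),
                 part_of = canon_edges(part_of, "part", "whole"),
                 subsets = subsets, xrefs = xrefs,
                 equivalences = canon_equiv(equivalences),
                 synonyms = synonyms),
            class = "ontology_graph")
}

empty_edges <- function(a, b) {
  df <- data.frame(x = character(), y = character(), stringsAsFactors = FALSE)
  names(df) <- c(a, b)
  df
}

canon_edges <- function(df, a, b) {
  if (is.null(df) || nrow(df) == 0L) return(empty_edges(a, b))
  df <- df[, c(a, b)]
  df <- unique(df)
  df <- df[order(df[[a]], df[[b]]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

empty_equiv <- function() data.frame(left = character(), right = character(),
                                     provenance = character(),
                                     stringsAsFactors = FALSE)

canon_equiv <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return(empty_equiv())
  if (!"provenance" %in% names(df)) df$provenance <- "asserted"
  lo <- pmin(df$left, df$right)
  hi <- pmax(df$left, df$right)
  df <- data.frame(left = lo, right = hi, provenance = df$provenance,
                   stringsAsFactors = FALSE)
  df <- df[df$left != df$right, , drop = FALSE]
  df <- df[!duplicated(df[, c("left", "right")]), , drop = FALSE]
  df <- df[order(df$left, df$right), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("ontology graph:", length(x$classes), "classes,",
      nrow(x$is_a), "is_a edges,", nrow(x$part_of), "part_of edges,",
      nrow(x$equivalences), "equivalences\n")
  invisible(x)
}

#' Build an ontology graph from a parsed OBO document
#'
#' Non-obsolete `[Term]` stanzas become classes; `is_a` tags become subclass
#' edges, `relationship: part_of` tags partonomy edges. `subset`, `xref` and
#' exact synonym content is carried over for bridging.
#'
#' @param doc An [obo_document()].
#' @return An [ontology_graph()].
#' @export
graph_from_obo <- function(doc) {
  stopifnot(inherits(doc, "obo_document"))
  keep <- !vapply(doc$stanzas, function(s) s$is_obsolete, logical(1))
  st <- doc$stanzas[keep]
  ids <- vapply(st, function(s) s$id, character(1))
  labs <- vapply(st, function(s) if (is.na(s$name)) "" else s$name, character(1))
  names(labs) <- ids
  labs <- labs[nzchar(labs)]
  isa <- do.call(rbind, lapply(st, function(s)
    if (length(s$is_a)) data.frame(child = s$id, parent = s$is_a,
                                   stringsAsFactors = FALSE)))
  po <- do.call(rbind, lapply(st, function(s) {
    r <- s$relationships
    r <- r[r$relation == "part_of", , drop = FALSE]
    if (nrow(r)) data.frame(part = s$id, whole = r$target,
                            stringsAsFactors = FALSE)
  }))
  subsets <- Filter(length, stats::setNames(lapply(st, `[[`, "subsets"), ids))
  xrefs <- Filter(length, stats::setNames(lapply(st, `[[`, "xrefs"), ids))
  synonyms <- Filter(length, stats::setNames(lapply(st, extract_exact_synonyms), ids))
  ontology_graph(classes = ids, labels = labs,
                 is_a = if (is.null(isa)) empty_edges("child", "parent") else isa,
                 part_of = if (is.null(po)) empty_edges("part", "whole") else po,
                 subsets = subsets, xrefs = xrefs, synonyms = synonyms)
}

extract_exact_synonyms <- function(s) {
  syn <- grep("^synonym: ", s$other, value = TRUE)
  syn <- syn[grepl("\"\\s+EXACT", syn)]
  sub("^synonym: \"(.*)\"\\s+EXACT.*$", "\\1", syn)
}

#' Merge ontology graphs under bridging equivalences
#'
#' Forms the union of nodes and edges of several graphs; each equivalence
#' axiom contracts its two classes into one group for closure purposes.
#' Axioms referencing a class absent from the union are skipped with a
#' warning and recorded in the `skipped_equivalences` attribute.
#'
#' @param graphs List of [ontology_graph()] objects.
#' @param equivalences Data frame of equivalence axioms (`left`, `right`,
#'   optionally `provenance`), e.g. from [build_uberon_bridge()] or
#'   [lexical_align()].
#' @return A merged [ontology_graph()].
#' @export
merge_graphs <- function(graphs, equivalences = empty_equiv()) {
  stopifnot(is.list(graphs), all(vapply(graphs, inherits, logical(1), "ontology_graph")))
  classes <- sort(unique(unlist(lapply(graphs, `[[`, "classes"))))
  labels <- unlist(lapply(rev(graphs), `[[`, "labels"))   # first graph wins
  labels <- labels[!duplicated(names(labels), fromLast = TRUE)]
  isa <- do.call(rbind, c(lapply(graphs, `[[`, "is_a"),
                          list(empty_edges("child", "parent"))))
  po <- do.call(rbind, c(lapply(graphs, `[[`, "part_of"),
                         list(empty_edges("part", "whole"))))
  subsets <- merge_named_lists(lapply(graphs, `[[`, "subsets"))
  xrefs <- merge_named_lists(lapply(graphs, `[[`, "xrefs"))
  synonyms <- merge_named_lists(lapply(graphs, `[[`, "synonyms"))
  eq <- canon_equiv(rbind(canon_equiv(equivalences),
                          do.call(rbind, lapply(graphs, `[[`, "equivalences"))))
  known <- eq$left %in% classes & eq$right %in% classes
  skipped <- eq[!known, , drop = FALSE]
  if (nrow(skipped))
    warning("skipping ", nrow(skipped),
            " equivalence axiom(s) referencing unknown classes")
  g <- ontology_graph(classes = classes, labels = labels, is_a = isa,
                      part_of = po, subsets = subsets, xrefs = xrefs,
                      equivalences = eq[known, , drop = FALSE],
                      synonyms = synonyms)
  attr(g, "skipped_equivalences") <- skipped
  g
}

merge_named_lists <- function(lists) {
  out <- list()
  for (l in lists) for (nm in names(l))
    out[[nm]] <- sort(unique(c(out[[nm]], l[[nm]])))
  out
}

# ---- closure ---------------------------------------------------------------

#' Reflexive-transitive subclass closure
#'
#' Contracts equivalence groups, verifies that the contracted `is_a` graph
#' is acyclic (a cycle among non-equivalent classes is an error), and
#' precomputes reachability so that [is_subclass_of()] queries are O(1)
#' lookups. Two entity modes are prepared: `is_a_only` (default,
#' conservative) and `is_a_plus_part_of` (is_a and part_of reachability
#' combined, for bearer-entity subsumption).
#'
#' @param graph An [ontology_graph()].
#' @return An object of class `subsumption_closure`.
#' @export
subclass_closure <- function(graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  classes <- graph$classes
  rep_of <- contract_equivalences(classes, graph$equivalences)

  map_edges <- function(from, to) {
    if (!length(from)) return(NULL)
    df <- unique(data.frame(from = unname(rep_of[from]), to = unname(rep_of[to]),
                            stringsAsFactors = FALSE))
    df[df$from != df$to, , drop = FALSE]
  }
  reps <- sort(unique(unname(rep_of)))
  isa <- map_edges(graph$is_a$child, graph$is_a$parent)
  g_isa <- igraph::graph_from_data_frame(
    if (is.null(isa)) data.frame(from = character(), to = character()) else isa,
    directed = TRUE, vertices = reps)
  if (!igraph::is_dag(g_isa))
    stop("is_a cycle among non-equivalent classes after equivalence contraction")
  po <- map_edges(graph$part_of$part, graph$part_of$whole)
  both <- rbind(isa, po)
  if (is.null(both)) both <- data.frame(from = character(), to = character())
  g_both <- igraph::graph_from_data_frame(both, directed = TRUE,
                                          vertices = reps)

  reach_sets <- function(g) {
    res <- igraph::ego(g, order = igraph::vcount(g), mode = "out")
    stats::setNames(lapply(res, function(v) names(v)), igraph::V(g)$name)
  }
  structure(list(classes = classes,
                 rep_of = rep_of,
                 members = split(names(rep_of), unname(rep_of)),
                 anc = list(is_a_only = reach_sets(g_isa),
                            is_a_plus_part_of = reach_sets(g_both))),
            class = "subsumption_closure")
}

contract_equivalences <- function(classes, equiv) {
  parent <- stats::setNames(classes, classes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (nrow(equiv)) for (i in seq_len(nrow(equiv))) {
    a <- find(equiv$left[i]); b <- find(equiv$right[i])
    if (a != b) parent[[max(a, b)]] <- min(a, b)  # smallest id is the rep
  }
  stats::setNames(vapply(classes, find, character(1)), classes)
}

#' @export
print.subsumption_closure <- function(x, ...) {
  cat("subsumption closure over", length(x$classes), "classes (",
      length(unique(x$rep_of)), "equivalence groups )\n")
  invisible(x)
}

#' Query the subclass closure
#'
#' @param closure A [subclass_closure()] object.
#' @param a,b Class CURIEs.
#' @param mode `"is_a_only"` (default) or `"is_a_plus_part_of"`.
#' @return `TRUE` iff `a` is a (reflexive-transitive, equivalence-aware)
#'   subclass of `b`. Querying an unknown CURIE is an error naming it.
#' @export
is_subclass_of <- function(closure, a, b,
                           mode = c("is_a_only", "is_a_plus_part_of")) {
  mode <- match.arg(mode)
  stopifnot(inherits(closure, "subsumption_closure"))
  for (x in c(a, b)) if (!x %in% closure$classes)
    stop("unknown class in subsumption query: ", x)
  closure$rep_of[[b]] %in% closure$anc[[mode]][[closure$rep_of[[a]]]]
}

#' All superclasses of a class
#'
#' @inheritParams is_subclass_of
#' @return Character vector of all classes subsuming `a` (including `a`
#'   itself and all members of equivalence groups).
#' @export
superclasses_of <- function(closure, a,
                            mode = c("is_a_only", "is_a_plus_part_of")) {
  mode <- match.arg(mode)
  if (!a %in% closure$classes) stop("unknown class in subsumption query: ", a)
  reps <- closure$anc[[mode]][[closure$rep_of[[a]]]]
  sort(unique(unlist(closure$members[reps], use.names = FALSE)))
}
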