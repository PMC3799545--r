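# Bridging axioms that let reasoning cross species: Uberon cross-reference
# equivalences to species anatomy ontologies, and lexical HP<->MP label
# alignments. Both generators are pure functions of their input graphs.

#' Uberon-to-species-anatomy bridge axioms
#'
#' One equivalence axiom per (Uberon class, cross-reference) where the
#' cross-reference prefix is in `target_prefixes` and the Uberon class is
#' not a member of the `upper_level` subset (very general terms such as
#' "tissue" are excluded from bridging). Only cross-references declared on
#' the Uberon class are used.
#'
#' @param uberon An [ontology_graph()] carrying xrefs and subset
#'   membership.
#' @param target_prefixes Character vector of anatomy-ontology prefixes
#'   (default ZFA, MA, FMA).
#' @param excluded_subset Subset name marking classes excluded from
#'   bridging.
#' @return Data frame `left` (Uberon CURIE), `right` (anatomy CURIE),
#'   `provenance` (`"uberon_xref"`), sorted.
#' @export
build_uberon_bridge <- function(uberon, target_prefixes = c("ZFA", "MA", "FMA"),
                                excluded_subset = "upper_level") {
  stopifnot(inherits(uberon, "ontology_graph"))
  out <- empty_equiv()
  for (id in names(uberon$xrefs)) {
    if (excluded_subset %in% (uberon$subsets[[id]] %||% character())) next
    hits <- uberon$xrefs[[id]]
    hits <- hits[curie_prefix(hits) %in% target_prefixes]
    for (h in hits)
      out[nrow(out) + 1L, ] <- list(id, h, "uberon_xref")
  }
  canon_equiv(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

normalize_label <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9 ]+", " ", x)
  trimws(gsub("\\s+", " ", x))
}

#' Lexical label alignment between two ontologies
#'
#' Generates an equivalence axiom for every pair of classes whose
#' normalized labels (lowercase, punctuation stripped, whitespace
#' collapsed) are equal. A label matching more than one class on either
#' side produces no axiom (ambiguity guard), and no axiom ever links two
#' classes with the same CURIE prefix. Matching is exact-label only;
#' `use_synonyms = TRUE` additionally admits exact synonyms (default off).
#'
#' @param left_onto,right_onto [ontology_graph()] objects carrying labels.
#' @param use_synonyms Also match exact synonyms.
#' @return Data frame `left`, `right`, `provenance` (`"lexical"`), sorted.
#' @export
lexical_align <- function(left_onto, right_onto, use_synonyms = FALSE) {
  name_table <- function(g) {
    ids <- names(g$labels)
    df <- data.frame(id = ids, norm = normalize_label(unname(g$labels)),
                     stringsAsFactors = FALSE)
    if (use_synonyms && length(g$synonyms)) {
      syn <- do.call(rbind, lapply(names(g$synonyms), function(id)
        data.frame(id = id, norm = normalize_label(g$synonyms[[id]]),
                   stringsAsFactors = FALSE)))
      df <- unique(rbind(df, syn))
    }
    df[nzchar(df$norm), , drop = FALSE]
  }
  lt <- name_table(left_onto)
  rt <- name_table(right_onto)
  # ambiguity guard: a normalized label naming > 1 class on a side is out
  unambiguous <- function(df) {
    cnt <- table(unique(df[, c("id", "norm")])$norm)
    df[df$norm %in% names(cnt)[cnt == 1L], , drop = FALSE]
  }
  lt <- unambiguous(lt)
  rt <- unambiguous(rt)
  hit <- merge(lt, rt, by = "norm", suffixes = c(".l", ".r"))
  hit <- hit[curie_prefix(hit$id.l) != curie_prefix(hit$id.r), , drop = FALSE]
  if (!nrow(hit)) return(empty_equiv())
  canon_equiv(data.frame(left = hit$id.l, right = hit$id.r,
                         provenance = "lexical", stringsAsFactors = FALSE))
}

#' Write equivalence axioms as a three-column TSV
#'
#' @param axioms Data frame `left`, `right`, `provenance`.
#' @param path Output path.
#' @return Invisibly, the lines written.
#' @export
write_equivalences <- function(axioms, path) {
  lines <- sprintf("%s\t%s\t%s", axioms$left, axioms$right, axioms$provenance)
  writeLines(lines, path)
  invisible(lines)
}
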