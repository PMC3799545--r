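# Cluster merging and OBO export of the cross-species phenotype ontology.
#
# Every equivalence group of the classification collapses into one class:
# the HPO identifier is primary when present (prefix priority HP > MP > ZP,
# lexicographic tie-break), the other member ids become alt_id entries.
# The subclass DAG is rewritten onto primary ids and transitively reduced
# before export; building-block classes never reach the exported file.

PHENO_PREFIXES <- c("HP", "MP", "ZP")

curie_prefix <- function(x) sub(":.*$", "", x)

#' Merge equivalence clusters into primary classes
#'
#' @param result A `subsumption_result` from [classify()].
#' @param labels Named character vector CURIE -> label.
#' @return A list with `clusters` (list of `pheno_cluster` objects:
#'   `members`, `primary_id`, `alt_ids`, `label`), `primary_of` (named
#'   character vector member -> primary) and `dag` (data frame `child`,
#'   `parent` over primary ids, transitively reduced).
#' @export
merge_clusters <- function(result, labels = character()) {
  stopifnot(inherits(result, "subsumption_result"))
  clusters <- lapply(result$equivalence_groups, function(members) {
    primary <- pick_primary(members)
    structure(list(members = sort(members), primary_id = primary,
                   alt_ids = sort(setdiff(members, primary)),
                   label = if (primary %in% names(labels)) labels[[primary]]
                           else NA_character_),
              class = "pheno_cluster")
  })
  primaries <- vapply(clusters, `[[`, character(1), "primary_id")
  clusters <- clusters[order(primaries)]
  primaries <- sort(primaries)
  primary_of <- stats::setNames(
    unlist(lapply(clusters, function(cl)
      rep(cl$primary_id, length(cl$members)))),
    unlist(lapply(clusters, `[[`, "members")))

  # strict closure on primaries
  M <- result$matrix
  pm <- matrix(FALSE, length(primaries), length(primaries),
               dimnames = list(primaries, primaries))
  idx <- which(M, arr.ind = TRUE)
  if (nrow(idx)) {
    ids <- rownames(M)
    ps <- unname(primary_of[ids[idx[, 1]]])
    pt <- unname(primary_of[ids[idx[, 2]]])
    keep <- ps != pt
    if (any(keep)) pm[cbind(ps[keep], pt[keep])] <- TRUE
  }
  dag <- transitive_reduction(pm)
  list(clusters = clusters, primary_of = primary_of, dag = dag)
}

pick_primary <- function(members) {
  pref <- curie_prefix(members)
  for (p in c(PHENO_PREFIXES)) {
    hit <- sort(members[pref == p])
    if (length(hit)) return(hit[1])
  }
  sort(members)[1]
}

# Input: strict transitively-closed boolean matrix over a DAG's nodes.
# Keep edge u->v iff no intermediate w with u->w and w->v.
transitive_reduction <- function(C) {
  ids <- rownames(C)
  edges <- empty_edges("child", "parent")
  idx <- which(C, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    u <- idx[k, 1]; v <- idx[k, 2]
    if (!any(C[u, ] & C[, v])) {
      edges[nrow(edges) + 1L, ] <- list(ids[u], ids[v])
    }
  }
  canon_edges(edges, "child", "parent")
}

#' Export the merged cross-species phenotype ontology
#'
#' Produces an OBO document containing only phenotype classes (HP/MP/ZP
#' prefixes): one stanza per cluster, carrying the cluster's alt_ids and
#' the is_a edges of the reduced DAG. Building-block classes are absent by
#' construction. A single root class (reserved `CP:` namespace) is added by
#' default so that otherwise parentless clusters hang off a connected DAG.
#'
#' @param merged Result of [merge_clusters()].
#' @param add_root Add the root class and link parentless clusters to it.
#' @param root_id,root_name Identity of the added root class.
#' @param header Header for the output document.
#' @return An [obo_document()].
#' @export
export_cross_species <- function(merged, add_root = TRUE,
                                 root_id = "CP:0000001",
                                 root_name = "cross-species phenotype",
                                 header = c("format-version" = "1.2",
                                            ontology = "crossSpeciesPheno")) {
  clusters <- merged$clusters
  dag <- merged$dag
  primaries <- vapply(clusters, `[[`, character(1), "primary_id")
  bad <- setdiff(unique(c(dag$child, dag$parent)), primaries)
  if (length(bad))
    stop("reduced DAG touches non-primary id(s): ", paste(bad, collapse = ", "))
  nonpheno <- primaries[!curie_prefix(primaries) %in% PHENO_PREFIXES]
  if (length(nonpheno))
    stop("non-phenotype class in export: ", paste(nonpheno, collapse = ", "))
  stanzas <- lapply(clusters, function(cl) {
    parents <- dag$parent[dag$child == cl$primary_id]
    if (add_root && !length(parents)) parents <- root_id
    obo_stanza(cl$primary_id,
               name = if (is.na(cl$label)) cl$primary_id else cl$label,
               is_a = parents, alt_ids = cl$alt_ids)
  })
  if (add_root && length(stanzas))
    stanzas <- c(stanzas, list(obo_stanza(root_id, name = root_name)))
  obo_document(stanzas = stanzas, header = header)
}

#' Resolve a phenotype id to its cluster primary id
#'
#' @param merged Result of [merge_clusters()].
#' @param ids Character vector of phenotype CURIEs (primary or alt).
#' @return Character vector of primary ids; `NA` where unresolvable.
#' @export
resolve_primary <- function(merged, ids) {
  out <- unname(merged$primary_of[ids])
  out[!ids %in% names(merged$primary_of)] <- NA_character_
  out
}
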