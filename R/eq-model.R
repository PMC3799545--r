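# Entity-Quality (EQ) logical definitions.
#
# A phenotype class is defined as the intersection of a PATO quality
# (the genus), a bearer entity reached via inheres_in, an optional towards
# entity (e.g. a ChEBI chemical), and the qualifier "abnormal"
# (PATO:0000460). Every definition is understood under the shared
# "has_part some" wrapper; since all phenotype classes carry the same
# wrapper it cancels in pairwise subsumption and is never materialized.

PATO_ABNORMAL <- "PATO:0000460"

#' Create an EQ definition
#'
#' @param defined_class CURIE of the class being defined (HP:/MP:/ZP:/GO:).
#' @param quality CURIE of the genus quality (mandatory).
#' @param bearer Optional CURIE of the bearer entity (anatomy or GO
#'   process), linked by `inheres_in`.
#' @param towards Optional CURIE of the `towards` entity (e.g. ChEBI).
#' @param qualifier Optional CURIE; after normalization always
#'   `PATO:0000460` ("abnormal") for phenotype classes.
#' @param extra_entities Data frame with columns `relation`, `target` for
#'   any additional differentia.
#' @return An object of class `eq_definition`.
#' @export
eq_definition <- function(defined_class, quality, bearer = NA_character_,
                          towards = NA_character_, qualifier = NA_character_,
                          extra_entities = empty_rel()) {
  stopifnot(is.character(defined_class), length(defined_class) == 1L,
            is.character(quality), length(quality) == 1L, !is.na(quality))
  structure(list(defined_class = defined_class, quality = quality,
                 bearer = as.character(bearer), towards = as.character(towards),
                 qualifier = as.character(qualifier),
                 extra_entities = unique_rel(extra_entities)),
            class = "eq_definition")
}

#' @export
print.eq_definition <- function(x, ...) {
  cat(x$defined_class, "= ", x$quality)
  if (!is.na(x$bearer)) cat(" and inheres_in some", x$bearer)
  if (!is.na(x$towards)) cat(" and towards some", x$towards)
  if (!is.na(x$qualifier)) cat(" and qualifier some", x$qualifier)
  if (nrow(x$extra_entities))
    cat("", paste0("and ", x$extra_entities$relation, " some ",
                   x$extra_entities$target), sep = " ")
  cat("\n")
  invisible(x)
}

#' Default relation-normalization map
#'
#' Relations that logical-definition files use in the bearer position are
#' declared sub-properties of `inheres_in`, mirroring the extra-equivalence
#' normalization applied before reasoning. The map is name -> normalizes_to;
#' chains are resolved to their fixed point and must terminate.
#'
#' @return Named character vector.
#' @export
default_relmap <- function() {
  c(occurs_in = "inheres_in",
    results_in_morphogenesis_of = "inheres_in",
    results_in_development_of = "inheres_in",
    inheres_in_part_of = "inheres_in")
}

resolve_relmap <- function(relmap) {
  out <- stats::setNames(character(0), character(0))
  for (nm in names(relmap)) {
    seen <- nm; cur <- nm
    while (cur %in% names(relmap)) {
      cur <- relmap[[cur]]
      if (cur %in% seen) stop("cycle in relation normalization map at: ", nm)
      seen <- c(seen, cur)
    }
    out[[nm]] <- cur
  }
  out
}

normalize_relation <- function(rel, relmap) {
  ifelse(rel %in% names(relmap), unname(relmap[rel]), rel)
}

#' Parse a cross-product ("xp") OBO document into EQ definitions
#'
#' Each stanza carrying `intersection_of` tags yields one definition: the
#' bare-CURIE genus becomes the quality, the `inheres_in` filler the bearer,
#' `towards` and `qualifier` fillers their named slots, and all other pairs
#' `extra_entities`. Stanzas without `intersection_of` are skipped and
#' counted; stanzas with zero or multiple genus entries are rejected with a
#' report entry. Additional `inheres_in` fillers beyond the first stay in
#' `extra_entities`.
#'
#' @param doc An [obo_document()].
#' @return A list with elements `definitions` (named list of
#'   [eq_definition()]), `n_skipped` (stanzas without intersection_of) and
#'   `report` (data frame `id`, `reason` of rejected stanzas).
#' @export
parse_xp_file <- function(doc) {
  stopifnot(inherits(doc, "obo_document"))
  defs <- list()
  n_skipped <- 0L
  report <- data.frame(id = character(), reason = character(),
                       stringsAsFactors = FALSE)
  for (s in doc$stanzas) {
    io <- s$intersection_of
    if (is.null(io) || nrow(io) == 0L) { n_skipped <- n_skipped + 1L; next }
    genus <- io$target[is.na(io$relation)]
    if (length(genus) != 1L) {
      report[nrow(report) + 1L, ] <- list(
        s$id, if (length(genus)) "multiple genus entries" else "no genus entry")
      next
    }
    diff <- io[!is.na(io$relation), , drop = FALSE]
    bearer <- towards <- qualifier <- NA_character_
    extra <- empty_rel()
    for (i in seq_len(nrow(diff))) {
      rel <- diff$relation[i]; tgt <- diff$target[i]
      if (rel == "inheres_in" && is.na(bearer)) bearer <- tgt
      else if (rel == "towards" && is.na(towards)) towards <- tgt
      else if (rel == "qualifier" && is.na(qualifier)) qualifier <- tgt
      else extra[nrow(extra) + 1L, ] <- list(rel, tgt)
    }
    defs[[s$id]] <- eq_definition(s$id, quality = genus, bearer = bearer,
                                  towards = towards, qualifier = qualifier,
                                  extra_entities = extra)
  }
  list(definitions = defs, n_skipped = n_skipped, report = report)
}

#' Normalize EQ definitions
#'
#' Guarantees consistency before reasoning: every definition receives the
#' qualifier "abnormal" (`PATO:0000460`) if it lacks one, and every extra
#' relation whose normalization chain ends at `inheres_in` has its filler
#' moved to the bearer position when the bearer slot is empty (otherwise it
#' is kept as an `inheres_in` extra differentia). The operation is
#' idempotent.
#'
#' @param defs Named list of [eq_definition()] (or the result of
#'   [parse_xp_file()]).
#' @param relmap Relation-normalization map, see [default_relmap()].
#' @return A list with elements `definitions` and `report` (data frame of
#'   definitions where a second bearer was demoted to an extra differentia).
#' @export
normalize_definitions <- function(defs, relmap = default_relmap()) {
  if (is.list(defs) && !is.null(defs$definitions)) defs <- defs$definitions
  relmap <- resolve_relmap(relmap)
  report <- data.frame(id = character(), reason = character(),
                       stringsAsFactors = FALSE)
  out <- lapply(defs, function(d) {
    if (is.na(d$qualifier)) d$qualifier <- PATO_ABNORMAL
    ex <- d$extra_entities
    if (nrow(ex)) {
      ex$relation <- normalize_relation(ex$relation, relmap)
      inh <- ex$relation == "inheres_in"
      if (any(inh)) {
        if (is.na(d$bearer)) {
          first <- which(inh)[1]
          d$bearer <- ex$target[first]
          ex <- ex[-first, , drop = FALSE]
          if (sum(inh) > 1L)
            report[nrow(report) + 1L, ] <<- list(d$defined_class,
                                                 "multiple bearers; first wins")
        } else {
          report[nrow(report) + 1L, ] <<- list(d$defined_class,
                                               "extra bearer kept as differentia")
        }
      }
      d$extra_entities <- unique_rel(ex)
    }
    d
  })
  report <- report[!duplicated(report), , drop = FALSE]
  list(definitions = out, report = report)
}

#' Serialize an EQ definition back to a term stanza
#'
#' Inverse of the [parse_xp_file()] mapping: genus plus (relation, filler)
#' pairs under `intersection_of`.
#'
#' @param def An [eq_definition()].
#' @param name Optional term label.
#' @return An [obo_stanza()].
#' @export
xp_stanza <- function(def, name = NA_character_) {
  io <- data.frame(relation = NA_character_, target = def$quality,
                   stringsAsFactors = FALSE)
  add <- function(rel, tgt) {
    if (length(tgt) == 1L && !is.na(tgt))
      io[nrow(io) + 1L, ] <<- list(rel, tgt)
  }
  add("inheres_in", def$bearer)
  add("towards", def$towards)
  add("qualifier", def$qualifier)
  ex <- def$extra_entities
  for (i in seq_len(nrow(ex))) io[nrow(io) + 1L, ] <- list(ex$relation[i], ex$target[i])
  obo_stanza(def$defined_class, name = name, intersection_of = io)
}
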