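# OBO 1.2-style flat-file reader/writer.
#
# Only the tag subset used by phenotype cross-product files is interpreted
# (id, name, is_a, relationship, alt_id, xref, subset, intersection_of,
# is_obsolete); every other tag is carried opaquely so that metadata
# survives a round trip. CURIEs are opaque "PREFIX:LOCAL" strings; no IRI
# expansion is performed.

CURIE_RE <- "[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.-]+"

#' Create a term stanza
#'
#' In-memory representation of one `[Term]` stanza of an OBO document.
#'
#' @param id Term CURIE, e.g. `"HP:0005609"`.
#' @param name Term label, or `NA`.
#' @param is_a Character vector of parent CURIEs.
#' @param relationships Data frame with columns `relation`, `target`
#'   (e.g. `part_of` edges).
#' @param alt_ids Character vector of merged secondary CURIEs.
#' @param xrefs Character vector of cross-referenced CURIEs.
#' @param subsets Character vector of subset names (e.g. `upper_level`).
#' @param intersection_of `NULL`, or a data frame with columns `relation`
#'   (`NA` for the genus entry) and `target` holding the logical-definition
#'   differentia.
#' @param is_obsolete Logical flag; obsolete terms carry no `is_a` edges.
#' @param other Character vector of raw unrecognised `tag: value` lines,
#'   preserved verbatim.
#' @return An object of class `obo_stanza`.
#' @export
obo_stanza <- function(id, name = NA_character_, is_a = character(),
                       relationships = empty_rel(), alt_ids = character(),
                       xrefs = character(), subsets = character(),
                       intersection_of = NULL, is_obsolete = FALSE,
                       other = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  keep <- function(x) {
    x <- as.character(x)
    sort(unique(x[!is.na(x) & nzchar(x)]))
  }
  structure(list(
    id = id, name = as.character(name), is_a = keep(is_a),
    relationships = unique_rel(relationships),
    alt_ids = keep(alt_ids),
    xrefs = keep(xrefs),
    subsets = keep(subsets),
    intersection_of = intersection_of,
    is_obsolete = isTRUE(is_obsolete),
    other = sort(as.character(other))
  ), class = "obo_stanza")
}

empty_rel <- function() data.frame(relation = character(), target = character(),
                                   stringsAsFactors = FALSE)

unique_rel <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return(empty_rel())
  df <- unique(df[, c("relation", "target")])
  df <- df[order(df$relation, df$target), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Create an OBO document
#'
#' @param stanzas List of [obo_stanza()] objects.
#' @param header Named character vector of header `tag: value` pairs, in
#'   order of appearance. A `format-version` entry is supplied if missing.
#' @param typedefs List of character vectors, each the verbatim lines of a
#'   non-Term stanza (e.g. `[Typedef]`); recorded but not interpreted.
#' @return An object of class `obo_document`.
#' @export
obo_document <- function(stanzas = list(), header = c("format-version" = "1.2"),
                         typedefs = list()) {
  if (!"format-version" %in% names(header))
    header <- c("format-version" = "1.2", header)
  ids <- vapply(stanzas, function(s) s$id, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate term id(s) in document: ", paste(dup, collapse = ", "))
  structure(list(header = header, stanzas = stanzas[order(ids)],
                 typedefs = typedefs),
            class = "obo_document")
}

#' @export
print.obo_document <- function(x, ...) {
  cat("OBO document:", length(x$stanzas), "term stanza(s),",
      length(x$typedefs), "typedef stanza(s)\n")
  invisible(x)
}

strip_obo_comment <- function(line) sub("\\s*!.*$", "", line)

first_curie <- function(x) {
  m <- regmatches(x, regexpr(CURIE_RE, x))
  if (length(m)) m else NA_character_
}

# "OBO_REL:inheres_in" -> "inheres_in"; bare relation names pass through.
strip_relation_prefix <- function(rel) sub("^[A-Za-z_.]+:(?=[A-Za-z_])", "", rel, perl = TRUE)

#' Parse OBO-format text
#'
#' @param x A character vector of lines, a single string containing
#'   newlines, or the path of an existing file.
#' @return An [obo_document()].
#' @details Trailing `!` comments are stripped; tag order within a stanza is
#'   not significant; unknown tags are preserved opaquely. A duplicate term
#'   id is a hard error naming the id; a non-empty line that is neither a
#'   stanza start nor a `tag: value` pair is an error naming the line number.
#' @export
parse_obo <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1L) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else as.character(x)

  header <- character()
  stanzas <- list()
  typedefs <- list()
  cur <- NULL          # accumulating [Term] tag lines
  cur_raw <- NULL      # accumulating verbatim non-Term stanza
  in_term <- FALSE
  seen_header <- TRUE  # header region until first stanza

  flush_term <- function() {
    if (is.null(cur)) return()
    stanzas[[length(stanzas) + 1L]] <<- term_from_tags(cur)
    cur <<- NULL
  }
  flush_raw <- function() {
    if (is.null(cur_raw)) return()
    typedefs[[length(typedefs) + 1L]] <<- cur_raw
    cur_raw <<- NULL
  }

  for (i in seq_along(lines)) {
    raw <- lines[[i]]
    line <- trimws(strip_obo_comment(raw))
    if (grepl("^\\[", raw)) {
      flush_term(); flush_raw(); seen_header <- FALSE
      if (trimws(raw) == "[Term]") {
        in_term <- TRUE
        cur <- data.frame(tag = character(), value = character(),
                          line = integer(), stringsAsFactors = FALSE)
      } else {
        in_term <- FALSE
        cur_raw <- trimws(raw)
      }
      next
    }
    if (!nzchar(line)) next
    if (seen_header || in_term) {
      m <- regexpr("^([A-Za-z_][A-Za-z0-9_-]*):\\s*", line)
      if (m == -1L)
        stop("malformed tag line ", i, ": ", raw)
      tag <- sub(":.*$", "", line)
      value <- trimws(sub("^[A-Za-z_][A-Za-z0-9_-]*:\\s*", "", line))
      if (seen_header) {
        header[[length(header) + 1L]] <- value
        names(header)[length(header)] <- tag
      } else {
        cur[nrow(cur) + 1L, ] <- list(tag, value, i)
      }
    } else {
      # inside a non-Term stanza: keep verbatim
      cur_raw <- c(cur_raw, trimws(raw))
    }
  }
  flush_term(); flush_raw()
  obo_document(stanzas = stanzas, header = header, typedefs = typedefs)
}

term_from_tags <- function(tags) {
  val <- function(tag) tags$value[tags$tag == tag]
  id <- val("id")
  if (length(id) != 1L)
    stop("term stanza must have exactly one id tag (near line ",
         if (nrow(tags)) tags$line[1] else NA, ")")
  name <- val("name")
  is_a <- vapply(val("is_a"), first_curie, character(1), USE.NAMES = FALSE)
  rels <- empty_rel()
  for (v in val("relationship")) {
    parts <- strsplit(trimws(v), "\\s+")[[1]]
    if (length(parts) >= 2L)
      rels[nrow(rels) + 1L, ] <- list(strip_relation_prefix(parts[1]),
                                      first_curie(parts[2]))
  }
  xrefs <- vapply(val("xref"), first_curie, character(1), USE.NAMES = FALSE)
  xrefs <- xrefs[!is.na(xrefs)]
  io <- NULL
  iov <- val("intersection_of")
  if (length(iov)) {
    io <- data.frame(relation = character(), target = character(),
                     stringsAsFactors = FALSE)
    for (v in iov) {
      parts <- strsplit(trimws(v), "\\s+")[[1]]
      if (length(parts) == 1L) {
        io[nrow(io) + 1L, ] <- list(NA_character_, first_curie(parts[1]))
      } else {
        io[nrow(io) + 1L, ] <- list(strip_relation_prefix(parts[1]),
                                    first_curie(parts[2]))
      }
    }
  }
  obsolete <- any(tolower(val("is_obsolete")) == "true")
  if (obsolete) is_a <- character()   # obsolete terms carry no is_a edges
  known <- c("id", "name", "is_a", "relationship", "alt_id", "xref", "subset",
             "intersection_of", "is_obsolete")
  unknown <- !tags$tag %in% known
  other <- if (any(unknown)) paste0(tags$tag[unknown], ": ", tags$value[unknown])
           else character()
  obo_stanza(id = id,
             name = if (length(name)) name[1] else NA_character_,
             is_a = is_a[!is.na(is_a)],
             relationships = rels,
             alt_ids = val("alt_id"),
             xrefs = xrefs,
             subsets = val("subset"),
             intersection_of = io,
             is_obsolete = obsolete,
             other = other)
}

#' Write an OBO document
#'
#' Deterministic writer: stanzas are sorted by id and tags emitted in a
#' canonical order (id, name, alt_id, subset, xref, is_a, relationship,
#' intersection_of, is_obsolete, then preserved unknown tags), each list
#' sorted, so equal documents yield byte-identical output.
#'
#' @param doc An [obo_document()].
#' @param path Optional file path; when given, lines are written there.
#' @return Invisibly (when `path` given) or visibly, the character vector of
#'   output lines.
#' @export
write_obo <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "obo_document"))
  out <- paste0(names(doc$header), ": ", doc$header)
  ids <- vapply(doc$stanzas, function(s) s$id, character(1))
  for (s in doc$stanzas[order(ids)]) {
    if (is.null(s$id) || !nzchar(s$id)) stop("stanza lacking id")
    tag_lines <- function(tag, vals)
      if (length(vals)) paste0(tag, ": ", sort(vals)) else character()
    out <- c(out, "", "[Term]", paste0("id: ", s$id))
    if (length(s$name) && !is.na(s$name)) out <- c(out, paste0("name: ", s$name))
    out <- c(out, tag_lines("alt_id", s$alt_ids),
             tag_lines("subset", s$subsets),
             tag_lines("xref", s$xrefs),
             tag_lines("is_a", s$is_a))
    rel <- unique_rel(s$relationships)
    if (nrow(rel))
      out <- c(out, paste0("relationship: ", rel$relation, " ", rel$target))
    io <- s$intersection_of
    if (!is.null(io) && nrow(io)) {
      genus <- io$target[is.na(io$relation)]
      diff <- io[!is.na(io$relation), , drop = FALSE]
      diff <- diff[order(diff$relation, diff$target), , drop = FALSE]
      out <- c(out, tag_lines("intersection_of", genus),
               if (nrow(diff)) paste0("intersection_of: ", diff$relation,
                                      " ", diff$target))
    }
    if (isTRUE(s$is_obsolete)) out <- c(out, "is_obsolete: true")
    out <- c(out, sort(s$other))
  }
  for (td in doc$typedefs[order(vapply(doc$typedefs, paste, character(1), collapse = "\n"))])
    out <- c(out, "", td)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Test two OBO documents for semantic equality
#'
#' Compares ids, names, is_a, relationship, alt_id, subset, xref and
#' intersection_of content, ignoring tag order and whitespace.
#'
#' @param a,b [obo_document()] objects.
#' @return Logical scalar.
#' @export
obo_equal <- function(a, b) {
  identical(write_obo(a)[-seq_along(a$header)],
            write_obo(b)[-seq_along(b$header)])
}

#' Read an OBO file
#'
#' @param path File path.
#' @return An [obo_document()].
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("no such OBO file: ", path)
  parse_obo(readLines(path, warn = FALSE))
}
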