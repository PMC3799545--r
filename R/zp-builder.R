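# Synthesis of a pre-composed zebrafish phenotype ontology (ZP classes)
# from post-composed ZFIN-style annotation lines.
#
# Every unique abnormal (quality, entity) combination becomes one ZP class
# labelled "abnormal(ly) {quality label} {entity label}"; the gene-to-class
# annotation relation is emitted alongside. Identifier assignment is
# deterministic and, via a persisted id map, stable across releases.

#' Default column layout of the post-composed phenotype file
#'
#' The tested default is the printed 8-column layout: gene id, Entrez id,
#' gene symbol, entity CURIE, entity label, quality CURIE, quality label,
#' modifier tag. (The published file's tab separators are sometimes shown
#' as semicolons for legibility; the parser expects tabs.)
#'
#' @return Named integer vector column map.
#' @export
default_pheno_cols <- function() {
  c(gene_id = 1L, entrez = 2L, symbol = 3L, entity = 4L, entity_label = 5L,
    quality = 6L, quality_label = 7L, modifier = 8L)
}

#' Parse a post-composed phenotype annotation file
#'
#' @param x Path, single string or character vector of tab-separated lines.
#' @param col_map Named integer vector locating the required fields, see
#'   [default_pheno_cols()]. Lines must have at least `max(col_map)`
#'   columns; others are skipped with a report entry.
#' @return List with `annotations` (data frame with the named fields) and
#'   `report` (data frame `line`, `reason`).
#' @export
parse_pheno_file <- function(x, col_map = default_pheno_cols()) {
  lines <- slurp_lines(x)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  need <- max(col_map)
  report <- data.frame(line = integer(), reason = character(),
                       stringsAsFactors = FALSE)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < need) {
      report[nrow(report) + 1L, ] <- list(i, "wrong column count")
      next
    }
    rows[[i]] <- f[col_map]
  }
  keep <- !vapply(rows, is.null, logical(1))
  ann <- as.data.frame(do.call(rbind, rows[keep]), stringsAsFactors = FALSE)
  if (nrow(ann)) names(ann) <- names(col_map)
  else ann <- as.data.frame(stats::setNames(
    rep(list(character()), length(col_map)), names(col_map)))
  rownames(ann) <- NULL
  list(annotations = ann, report = report)
}

slurp_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    return(readLines(x, warn = FALSE))
  if (length(x) == 1L) return(strsplit(x, "\n", fixed = TRUE)[[1]])
  as.character(x)
}

zp_def_key <- function(quality, entity) paste(quality, entity, sep = "|")

zp_id_format <- function(n) sprintf("ZP:%07d", n)

#' Build the ZP ontology from post-composed annotations
#'
#' Only lines with modifier `"abnormal"` participate in class synthesis
#' (others are dropped and reported). Classes are deduplicated on
#' definition content, sorted by (quality CURIE, entity CURIE) and numbered
#' from `id_base`; definitions present in `id_map` keep their previous
#' identifiers, so ids are stable across releases.
#'
#' @param annots Data frame from [parse_pheno_file()]`$annotations`.
#' @param id_map Optional data frame `key`, `zp_id` from a previous run
#'   (the persisted two-column id-map file).
#' @param id_base Integer; first number used for novel definitions.
#' @param known_classes Optional character vector of loaded building-block
#'   CURIEs; annotations whose entity or quality is absent are reported
#'   (the class is still created).
#' @return List with `classes` (list of `zp_class` objects: `zp_id`,
#'   `label`, `definition`), `annotations` (data frame `gene_id`, `symbol`,
#'   `zp_id`, unique pairs), `id_map` (updated data frame `key`, `zp_id`)
#'   and `report` (data frame `item`, `reason`).
#' @export
build_zp_ontology <- function(annots, id_map = NULL, id_base = 1L,
                              known_classes = NULL) {
  report <- data.frame(item = character(), reason = character(),
                       stringsAsFactors = FALSE)
  normal <- annots$modifier != "abnormal"
  if (any(normal))
    report[nrow(report) + 1L, ] <- list(
      paste0(sum(normal), " line(s)"), "modifier not 'abnormal'; dropped")
  ab <- annots[!normal, , drop = FALSE]

  key <- zp_def_key(ab$quality, ab$entity)
  first <- !duplicated(key)
  defs <- data.frame(key = key[first], quality = ab$quality[first],
                     entity = ab$entity[first],
                     quality_label = ab$quality_label[first],
                     entity_label = ab$entity_label[first],
                     stringsAsFactors = FALSE)
  defs <- defs[order(defs$quality, defs$entity), , drop = FALSE]

  if (is.null(id_map))
    id_map <- data.frame(key = character(), zp_id = character(),
                         stringsAsFactors = FALSE)
  assigned <- stats::setNames(id_map$zp_id, id_map$key)
  used <- as.integer(sub("^ZP:", "", id_map$zp_id))
  nxt <- as.integer(id_base)
  zp_ids <- character(nrow(defs))
  for (i in seq_len(nrow(defs))) {
    k <- defs$key[i]
    if (k %in% names(assigned)) {
      zp_ids[i] <- assigned[[k]]
    } else {
      while (nxt %in% used) nxt <- nxt + 1L
      zp_ids[i] <- zp_id_format(nxt)
      used <- c(used, nxt)
      assigned[[k]] <- zp_ids[i]
    }
  }
  defs$zp_id <- zp_ids

  classes <- lapply(seq_len(nrow(defs)), function(i) {
    structure(list(
      zp_id = defs$zp_id[i],
      label = sprintf("abnormal(ly) %s %s",
                      defs$quality_label[i], defs$entity_label[i]),
      definition = eq_definition(defs$zp_id[i], quality = defs$quality[i],
                                 bearer = defs$entity[i],
                                 qualifier = PATO_ABNORMAL)),
      class = "zp_class")
  })
  names(classes) <- defs$zp_id

  if (!is.null(known_classes)) {
    miss <- sort(unique(c(defs$quality[!defs$quality %in% known_classes],
                          defs$entity[!defs$entity %in% known_classes])))
    for (m in miss)
      report[nrow(report) + 1L, ] <- list(m, "CURIE absent from loaded graphs")
  }

  id_of <- stats::setNames(defs$zp_id, defs$key)
  ann <- data.frame(gene_id = ab$gene_id, symbol = ab$symbol,
                    zp_id = unname(id_of[zp_def_key(ab$quality, ab$entity)]),
                    stringsAsFactors = FALSE)
  ann <- unique(ann)
  ann <- ann[order(ann$gene_id, ann$zp_id), , drop = FALSE]
  rownames(ann) <- NULL

  new_map <- data.frame(key = names(assigned), zp_id = unname(assigned),
                        stringsAsFactors = FALSE)
  new_map <- new_map[order(new_map$zp_id), , drop = FALSE]
  rownames(new_map) <- NULL
  list(classes = classes, annotations = ann, id_map = new_map, report = report)
}

#' Serialize ZP classes as an OBO document
#'
#' Each class carries its label and an `intersection_of` logical definition
#' (quality genus, `inheres_in` entity, abnormal qualifier), so the file
#' doubles as the cross-product file for the synthesized ontology.
#'
#' @param zp Result of [build_zp_ontology()].
#' @param header Document header.
#' @return An [obo_document()].
#' @export
zp_obo <- function(zp, header = c("format-version" = "1.2", ontology = "zp")) {
  stanzas <- lapply(zp$classes, function(cl) xp_stanza(cl$definition, name = cl$label))
  obo_document(stanzas = unname(stanzas), header = header)
}

#' Write the gene-to-ZP annotation table
#'
#' Three tab-separated columns: gene id, gene symbol, ZP id (the `zp.annot`
#' companion file of the synthesized ontology).
#'
#' @param zp Result of [build_zp_ontology()].
#' @param path Output file path.
#' @return Invisibly, the lines written.
#' @export
write_zp_annot <- function(zp, path) {
  lines <- sprintf("%s\t%s\t%s", zp$annotations$gene_id,
                   zp$annotations$symbol, zp$annotations$zp_id)
  writeLines(lines, path)
  invisible(lines)
}

#' Write or read the persisted ZP id map
#'
#' Two tab-separated columns: definition key (`quality|entity`), ZP id.
#'
#' @param id_map Data frame `key`, `zp_id`.
#' @param path File path.
#' @return `write_zp_idmap` invisibly returns the lines; `read_zp_idmap`
#'   the data frame (empty if the file does not exist).
#' @export
write_zp_idmap <- function(id_map, path) {
  lines <- sprintf("%s\t%s", id_map$key, id_map$zp_id)
  writeLines(lines, path)
  invisible(lines)
}

#' @rdname write_zp_idmap
#' @export
read_zp_idmap <- function(path) {
  if (!file.exists(path))
    return(data.frame(key = character(), zp_id = character(),
                      stringsAsFactors = FALSE))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(key = character(), zp_id = character(),
                      stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(key = parts[, 1], zp_id = parts[, 2], stringsAsFactors = FALSE)
}
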