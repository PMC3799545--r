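# Cross-species human-gene annotation: human genes receive HPO annotations
# through disease-to-gene maps (OMIM, Orphanet), and MPO/ZP annotations
# transferred from orthologous mouse and zebrafish genes. Phenotype ids are
# rewritten to cluster primary ids before output.

#' Default column maps for the orthology table dialects
#'
#' @return Named list of named integer vectors: `mouse` (human symbol,
#'   human Entrez, mouse symbol, MGI id) and `zebrafish` (ZFIN id, ZFIN
#'   symbol, human symbol, human Entrez).
#' @export
default_ortho_cols <- function() {
  list(mouse = c(human_symbol = 1L, human_entrez = 2L,
                 model_symbol = 3L, model_id = 4L),
       zebrafish = c(model_id = 1L, model_symbol = 2L,
                     human_symbol = 3L, human_entrez = 4L))
}

read_tsv_cols <- function(x, col_map, numeric_cols = character()) {
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
  df <- as.data.frame(do.call(rbind, rows[keep]), stringsAsFactors = FALSE)
  if (nrow(df)) names(df) <- names(col_map)
  else df <- as.data.frame(stats::setNames(
    rep(list(character()), length(col_map)), names(col_map)))
  for (nc in intersect(numeric_cols, names(df))) {
    suppressWarnings(v <- as.integer(df[[nc]]))
    bad <- is.na(v) & nzchar(df[[nc]])
    if (any(bad)) {
      report <- rbind(report, data.frame(line = which(keep)[bad],
                                         reason = paste0("non-numeric ", nc),
                                         stringsAsFactors = FALSE))
      df <- df[!bad, , drop = FALSE]
      v <- v[!bad]
    }
    df[[nc]] <- v
  }
  rownames(df) <- NULL
  list(table = df, report = report)
}

#' Load mouse and zebrafish orthology maps
#'
#' Reads the two orthology dialects (mouse marker report and ZFIN ortho
#' table) into one many-to-many model-gene to human-gene map, deduplicated.
#' Unparseable lines are skipped and reported.
#'
#' @param mouse_table,zfin_table Paths or character vectors of
#'   tab-separated lines.
#' @param col_maps Column maps per dialect, see [default_ortho_cols()].
#' @return An object of class `orthology_map`: list with `mouse` and
#'   `zebrafish` data frames (`model_id`, `model_symbol`, `human_entrez`,
#'   `human_symbol`) and `report`.
#' @export
load_orthology <- function(mouse_table, zfin_table,
                           col_maps = default_ortho_cols()) {
  m <- read_tsv_cols(mouse_table, col_maps$mouse, numeric_cols = "human_entrez")
  z <- read_tsv_cols(zfin_table, col_maps$zebrafish, numeric_cols = "human_entrez")
  tidy <- function(df) {
    df <- unique(df[, c("model_id", "model_symbol", "human_entrez", "human_symbol")])
    df <- df[order(df$model_id, df$human_entrez), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  tag <- function(df, source) {
    df$source <- rep(source, nrow(df))
    df
  }
  structure(list(mouse = tidy(m$table), zebrafish = tidy(z$table),
                 report = rbind(tag(m$report, "mouse"),
                                tag(z$report, "zebrafish"))),
            class = "orthology_map")
}

#' Human gene-phenotype annotations from disease data
#'
#' Joins the disease-to-phenotype file with the OMIM and Orphanet
#' disease-to-gene maps: each (disease, HPO term) meeting each (disease,
#' gene) yields one record, with the evidence source(s) accumulated. A
#' record supported by both databases appears once with evidence
#' `"OMIM,Orphanet"`. Diseases carrying phenotypes but no gene are dropped
#' and counted. Rows whose qualifier field is `NOT` are negative
#' annotations and skipped.
#'
#' @param disease_pheno Path/lines of the disease-phenotype table (columns:
#'   database, disease id, disease name, qualifier, HPO id).
#' @param omim_gene_map Path/lines of the OMIM disease-to-gene table
#'   (columns: MIM number, Entrez id, gene symbol).
#' @param orphanet_gene_map Path/lines of the simplified Orphanet table
#'   (columns: Orpha number, gene symbol); Entrez ids are resolved through
#'   the OMIM map's symbols, unresolvable genes are dropped and reported.
#' @return List with `records` (data frame `human_entrez`, `human_symbol`,
#'   `pheno_class`, `source_species` = "human", `source_gene_id` = NA,
#'   `source_gene_symbol` = NA, `evidence`) and `report` (named counts).
#' @export
human_gene_annotations <- function(disease_pheno, omim_gene_map,
                                   orphanet_gene_map = NULL) {
  dp <- read_tsv_cols(disease_pheno,
                      c(db = 1L, disease_id = 2L, disease_name = 3L,
                        qualifier = 4L, hpo = 5L))$table
  dp <- dp[toupper(dp$qualifier) != "NOT", , drop = FALSE]
  dp$disease <- paste0(toupper(dp$db), ":", dp$disease_id)

  om <- read_tsv_cols(omim_gene_map,
                      c(disease_id = 1L, entrez = 2L, symbol = 3L),
                      numeric_cols = "entrez")$table
  genes <- data.frame(disease = paste0("OMIM:", om$disease_id),
                      entrez = om$entrez, symbol = om$symbol,
                      evidence = "OMIM", stringsAsFactors = FALSE)
  n_unresolved <- 0L
  if (!is.null(orphanet_gene_map)) {
    op <- read_tsv_cols(orphanet_gene_map,
                        c(disease_id = 1L, symbol = 2L))$table
    sym2ent <- unique(om[, c("symbol", "entrez")])
    sym2ent <- stats::setNames(sym2ent$entrez, sym2ent$symbol)
    ent <- unname(sym2ent[op$symbol])
    n_unresolved <- sum(is.na(ent))
    keep <- !is.na(ent)
    if (any(keep))
      genes <- rbind(genes, data.frame(
        disease = paste0("ORPHA:", op$disease_id[keep]),
        entrez = ent[keep], symbol = op$symbol[keep],
        evidence = "Orphanet", stringsAsFactors = FALSE))
  }

  j <- merge(dp[, c("disease", "hpo")], genes, by = "disease")
  no_gene <- length(setdiff(unique(dp$disease), unique(genes$disease)))
  if (nrow(j)) {
    ev <- stats::aggregate(evidence ~ entrez + symbol + hpo, data = j,
                           FUN = function(e) paste(sort(unique(e)), collapse = ","))
    records <- data.frame(human_entrez = ev$entrez, human_symbol = ev$symbol,
                          pheno_class = ev$hpo, source_species = "human",
                          source_gene_id = NA_character_,
                          source_gene_symbol = NA_character_,
                          evidence = ev$evidence, stringsAsFactors = FALSE)
  } else records <- empty_annotation_records()
  records <- records[order(records$human_entrez, records$pheno_class,
                           records$evidence), , drop = FALSE]
  rownames(records) <- NULL
  list(records = records,
       report = c(diseases_without_gene = no_gene,
                  orphanet_unresolved_symbols = n_unresolved))
}

empty_annotation_records <- function() {
  data.frame(human_entrez = integer(), human_symbol = character(),
             pheno_class = character(), source_species = character(),
             source_gene_id = character(), source_gene_symbol = character(),
             evidence = character(), stringsAsFactors = FALSE)
}

#' Parse a genotype-level mouse phenotype report
#'
#' Dialect: tab-separated columns genotype, allele symbols, background,
#' MP id, PubMed id, comma-separated marker accession ids. Every marker
#' involved in the genotype receives the annotation (declared policy for
#' multi-gene genotypes; override via `col_map`).
#'
#' @param x Path or lines.
#' @param col_map Named integer vector with entries `mp_id` and `markers`.
#' @return List with `annotations` (data frame `model_id`, `pheno`) and
#'   `report`.
#' @export
parse_mouse_pheno <- function(x, col_map = c(mp_id = 4L, markers = 6L)) {
  r <- read_tsv_cols(x, col_map)
  tab <- r$table
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    markers <- trimws(strsplit(tab$markers[i], "[,|]")[[1]])
    markers <- markers[nzchar(markers)]
    if (!length(markers)) return(NULL)
    data.frame(model_id = markers, pheno = tab$mp_id[i], stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, c(rows, list(data.frame(model_id = character(),
                                                pheno = character(),
                                                stringsAsFactors = FALSE))))
  ann <- unique(ann)
  ann <- ann[order(ann$model_id, ann$pheno), , drop = FALSE]
  rownames(ann) <- NULL
  list(annotations = ann, report = r$report)
}

#' Transfer model-organism annotations to human genes via orthology
#'
#' Each (model gene, phenotype class) annotation fans out to every
#' orthologous human gene, producing one record per (human gene, class,
#' source gene). Phenotype ids are rewritten to cluster primary ids via the
#' alt_id lookup; annotations with no ortholog are dropped and counted, and
#' phenotype ids that do not resolve into the merged ontology are reported
#' and dropped.
#'
#' @param mouse_annots Data frame `model_id`, `pheno` (MP ids), e.g. from
#'   [parse_mouse_pheno()].
#' @param zp_annots Data frame `gene_id`, `symbol`, `zp_id` from
#'   [build_zp_ontology()].
#' @param ortho An `orthology_map` from [load_orthology()].
#' @param merged Result of [merge_clusters()] (for primary-id resolution).
#' @return List with `records` (same shape as [human_gene_annotations()],
#'   `source_species` mouse/zebrafish, `evidence` MGI/ZFIN) and `report`
#'   (named counts: annotations without ortholog, unresolvable ids,
#'   ortholog fan-out).
#' @export
transfer_model_annotations <- function(mouse_annots, zp_annots, ortho, merged) {
  one_species <- function(ann, map, species, evidence) {
    if (is.null(ann) || nrow(ann) == 0L)
      return(list(records = empty_annotation_records(),
                  no_ortholog = 0L, unresolved = character(), fan_out = 0L))
    primary <- resolve_primary(merged, ann$pheno)
    unresolved <- sort(unique(ann$pheno[is.na(primary)]))
    ann <- ann[!is.na(primary), , drop = FALSE]
    ann$primary <- primary[!is.na(primary)]
    j <- merge(ann, map, by = "model_id")
    no_ortholog <- sum(!ann$model_id %in% map$model_id)  # dropped annotations
    fan_out <- 0L
    if (nrow(j)) {
      per_gene <- tapply(j$human_entrez, j$model_id, function(v) length(unique(v)))
      fan_out <- sum(per_gene > 1L)
      rec <- data.frame(human_entrez = j$human_entrez,
                        human_symbol = j$human_symbol,
                        pheno_class = j$primary,
                        source_species = species,
                        source_gene_id = j$model_id,
                        source_gene_symbol = j$model_symbol,
                        evidence = evidence, stringsAsFactors = FALSE)
      rec <- unique(rec)
    } else rec <- empty_annotation_records()
    list(records = rec, no_ortholog = no_ortholog,
         unresolved = unresolved, fan_out = fan_out)
  }
  m <- one_species(mouse_annots, ortho$mouse, "mouse", "MGI")
  zp <- zp_annots
  if (!is.null(zp) && nrow(zp)) {
    zp <- data.frame(model_id = zp$gene_id, pheno = zp$zp_id,
                     stringsAsFactors = FALSE)
  }
  z <- one_species(zp, ortho$zebrafish, "zebrafish", "ZFIN")
  records <- rbind(m$records, z$records)
  records <- records[order(records$human_entrez, records$pheno_class,
                           records$source_species, records$source_gene_id), ,
                     drop = FALSE]
  rownames(records) <- NULL
  list(records = records,
       report = list(no_ortholog = c(mouse = m$no_ortholog, zebrafish = z$no_ortholog),
                     unresolved_pheno_ids = sort(unique(c(m$unresolved, z$unresolved))),
                     fan_out_genes = c(mouse = m$fan_out, zebrafish = z$fan_out)))
}

#' Combine and rewrite annotation records onto the merged ontology
#'
#' Human-sourced records' HPO ids are rewritten to cluster primaries;
#' records whose phenotype id cannot be resolved are dropped and reported.
#'
#' @param human Result of [human_gene_annotations()].
#' @param model Result of [transfer_model_annotations()].
#' @param merged Result of [merge_clusters()].
#' @return List with `records` (combined data frame) and `report`.
#' @export
combine_annotations <- function(human, model, merged) {
  h <- human$records
  primary <- resolve_primary(merged, h$pheno_class)
  unresolved <- sort(unique(h$pheno_class[is.na(primary)]))
  h$pheno_class <- primary
  h <- h[!is.na(h$pheno_class), , drop = FALSE]
  h <- h[order(h$human_entrez, h$pheno_class, h$evidence), , drop = FALSE]
  records <- rbind(h, model$records)
  rownames(records) <- NULL
  list(records = records,
       report = list(human_unresolved_pheno_ids = unresolved))
}

#' Write the cross-species human-gene annotation table
#'
#' Four tab-separated fields per row: human Entrez id, human gene symbol,
#' "label (CLASS:ID)", and the provenance field -- for model-organism rows
#' "sourceSymbol (sourceId/SPECIES)" with species tags `MOUSE`/`ZEBRAF`,
#' for human rows "(EVIDENCE/HUMAN)". Rows are sorted for determinism.
#'
#' @param records Combined annotation data frame.
#' @param labels Named character vector CURIE -> label for the merged
#'   ontology's primary ids.
#' @param path Output file path (conventionally
#'   `HSgenes_crossSpeciesPhenoAnnotation.txt`).
#' @return Invisibly, the lines written.
#' @export
write_hs_annotations <- function(records, labels, path = NULL) {
  lab <- ifelse(records$pheno_class %in% names(labels),
                unname(labels[records$pheno_class]), records$pheno_class)
  species_tag <- c(human = "HUMAN", mouse = "MOUSE", zebrafish = "ZEBRAF")
  src <- ifelse(records$source_species == "human",
                sprintf("(%s/HUMAN)", records$evidence),
                sprintf("%s (%s/%s)", records$source_gene_symbol,
                        records$source_gene_id,
                        species_tag[records$source_species]))
  lines <- sprintf("%d\t%s\t%s (%s)\t%s", records$human_entrez,
                   records$human_symbol, lab, records$pheno_class, src)
  lines <- sort(lines)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Per-source annotation count summary
#'
#' @param records Combined annotation data frame.
#' @return Data frame `statistic`, `count`: total, human (with OMIM and
#'   Orphanet evidence breakdown), mouse and zebrafish annotation counts.
#' @export
annotation_summary <- function(records) {
  is_h <- records$source_species == "human"
  data.frame(
    statistic = c("all_annotations", "human_annotations",
                  "human_omim_supported", "human_orphanet_supported",
                  "mouse_annotations", "zebrafish_annotations"),
    count = c(nrow(records), sum(is_h),
              sum(is_h & grepl("OMIM", records$evidence)),
              sum(is_h & grepl("Orphanet", records$evidence)),
              sum(records$source_species == "mouse"),
              sum(records$source_species == "zebrafish")),
    stringsAsFactors = FALSE)
}

#' Genes annotated to a phenotype class or its descendants
#'
#' Queries the exported ontology: resolves `class_id` through alt_ids,
#' collects all descendant classes via the exported is_a edges, and returns
#' the annotation records attached to any of them.
#'
#' @param records Combined annotation data frame (primary ids).
#' @param doc The exported [obo_document()] (`crossSpeciesPheno.obo`).
#' @param class_id Phenotype CURIE (primary or alt id).
#' @param include_descendants Include inferred subclasses (default TRUE).
#' @return Subset of `records`.
#' @export
genes_for_phenotype <- function(records, doc, class_id,
                                include_descendants = TRUE) {
  stopifnot(inherits(doc, "obo_document"))
  prim <- stats::setNames(
    rep(vapply(doc$stanzas, `[[`, character(1), "id"),
        lengths(lapply(doc$stanzas, `[[`, "alt_ids")) + 1L),
    unlist(lapply(doc$stanzas, function(s) c(s$id, s$alt_ids))))
  if (!class_id %in% names(prim))
    stop("unknown phenotype class: ", class_id)
  target <- prim[[class_id]]
  wanted <- target
  if (include_descendants) {
    edges <- do.call(rbind, lapply(doc$stanzas, function(s)
      if (length(s$is_a)) data.frame(child = s$id, parent = s$is_a,
                                     stringsAsFactors = FALSE)))
    if (!is.null(edges)) {
      repeat {
        more <- unique(edges$child[edges$parent %in% wanted])
        more <- setdiff(more, wanted)
        if (!length(more)) break
        wanted <- c(wanted, more)
      }
    }
  }
  records[records$pheno_class %in% wanted, , drop = FALSE]
}
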