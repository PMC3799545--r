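# Deterministic synthetic fixture sets: miniature building-block
# ontologies, cross-product files and annotation tables sufficient to run
# the whole construction pipeline without any download.
#
# The generator emulates the structural features the pipeline depends on:
# nested quality and anatomy hierarchies, three species-anatomy mirrors of
# one master tree bridged through Uberon cross-references, phenotype
# ontologies with a mix of defined and undefined classes, post-composed
# zebrafish annotations, orthology and disease tables. With
# `include_fig1_cases` it embeds two worked examples: a
# hypoglycemia/aldohexose inference driven by a single ChEBI edge, and a
# microphthalmia-style case in which a synthesized ZP class and an MP class
# are inferred under one HP class, with matching gene annotations in all
# three species.

#' Describe a synthetic fixture set
#'
#' @param seed Integer RNG seed; the same seed yields byte-identical files.
#' @param n_entities Classes per toy anatomy ontology (master tree size).
#' @param n_qualities Classes in the toy quality ontology.
#' @param depth Maximum hierarchy depth of the generated trees.
#' @param n_pheno_classes Phenotype classes per ontology (HP terms, MP
#'   terms, and distinct abnormal ZP combinations).
#' @param n_genes Genes per model species.
#' @param bridge_fraction Proportion of master anatomy classes given Uberon
#'   cross-references to all three species mirrors.
#' @param include_fig1_cases Embed the worked-example classes, axioms and
#'   annotation lines.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_entities = 12L, n_qualities = 8L,
                         depth = 3L, n_pheno_classes = 10L, n_genes = 8L,
                         bridge_fraction = 0.8, include_fig1_cases = TRUE) {
  stopifnot(n_entities >= 1L, n_qualities >= 1L, depth >= 1L,
            n_pheno_classes >= 1L, n_genes >= 1L,
            bridge_fraction >= 0, bridge_fraction <= 1,
            (n_qualities * n_entities) >= n_pheno_classes + 1L)
  structure(list(seed = as.integer(seed), n_entities = as.integer(n_entities),
                 n_qualities = as.integer(n_qualities), depth = as.integer(depth),
                 n_pheno_classes = as.integer(n_pheno_classes),
                 n_genes = as.integer(n_genes),
                 bridge_fraction = bridge_fraction,
                 include_fig1_cases = isTRUE(include_fig1_cases)),
            class = "fixture_spec")
}

# parent index vector of a random tree with capped depth (node 1 is root)
random_tree <- function(n, depth) {
  parent <- rep(NA_integer_, n)
  level <- integer(n)
  level[1] <- 1L
  for (i in seq_len(n)[-1]) {
    cand <- which(level[seq_len(i - 1L)] < depth)
    if (!length(cand)) cand <- 1L
    p <- if (length(cand) == 1L) cand else sample(cand, 1L)
    parent[i] <- p
    level[i] <- level[p] + 1L
  }
  parent
}

fx_id <- function(prefix, n) sprintf("%s:%07d", prefix, n)

tree_stanzas <- function(prefix, base, labels, parent) {
  lapply(seq_along(labels), function(i)
    obo_stanza(fx_id(prefix, base + i), name = labels[i],
               is_a = if (is.na(parent[i])) character()
                      else fx_id(prefix, base + parent[i])))
}

#' Generate a synthetic fixture directory
#'
#' Writes the toy PATO/ChEBI/GO/FMA/MA/ZFA/Uberon ontologies, HP/MP/GO
#' cross-product files, the post-composed zebrafish phenotype file,
#' orthology and mouse phenotype tables, disease maps and a `config.yaml`
#' ready for [run_pipeline()].
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the directory, the config path and the
#'   per-role file paths.
#' @export
generate_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  fig <- spec$include_fig1_cases
  p <- function(...) file.path(dir, ...)

  ## quality ontology (toy PATO) -------------------------------------------
  nq <- spec$n_qualities
  q_parent <- random_tree(nq, spec$depth)
  q_labels <- c("quality", if (nq > 1) paste("toy quality", seq_len(nq - 1L)))
  pato <- tree_stanzas("PATO", 200000L, q_labels, q_parent)
  pato <- c(pato, list(obo_stanza("PATO:0000460", name = "abnormal",
                                  is_a = fx_id("PATO", 200001L))))
  if (fig) {
    root <- fx_id("PATO", 200001L)
    pato <- c(pato, list(
      obo_stanza("PATO:0000033", name = "concentration of", is_a = root),
      obo_stanza("PATO:0001163", name = "decreased concentration",
                 is_a = "PATO:0000033"),
      obo_stanza("PATO:0000587", name = "decreased size", is_a = root),
      obo_stanza("PATO:0000645", name = "hypoplastic", is_a = "PATO:0000587"),
      obo_stanza("PATO:0001641", name = "decreased functionality", is_a = root),
      obo_stanza("PATO:0000014", name = "color", is_a = root)))
  }
  write_obo(obo_document(pato, c("format-version" = "1.2", ontology = "pato")),
            p("pato.obo"))

  ## chemical ontology (toy ChEBI) -----------------------------------------
  chebi <- list(obo_stanza("CHEBI:0100001", name = "chemical entity"))
  n_chem <- 4L
  for (i in seq_len(n_chem))
    chebi <- c(chebi, list(obo_stanza(fx_id("CHEBI", 100001L + i),
                                      name = paste("toy chemical", i),
                                      is_a = "CHEBI:0100001")))
  if (fig) {
    chebi <- c(chebi, list(
      obo_stanza("CHEBI:16646", name = "carbohydrate", is_a = "CHEBI:0100001"),
      obo_stanza("CHEBI:33917", name = "aldohexose", is_a = "CHEBI:16646"),
      obo_stanza("CHEBI:17234", name = "glucose", is_a = "CHEBI:33917")))
  }
  write_obo(obo_document(chebi, c("format-version" = "1.2", ontology = "chebi")),
            p("chebi.obo"))

  ## anatomy: one master tree mirrored per species, bridged via Uberon -----
  ne <- spec$n_entities
  a_parent <- random_tree(ne, spec$depth)
  a_labels <- c("anatomical structure",
                if (ne > 1) paste("toy organ", seq_len(ne - 1L)))
  species_extra <- list(
    ZFA = list(list("ZFA:0000107", "eye", NULL),
               list("ZFA:0000208", "gall bladder", NULL)),
    MA = list(list("MA:0000261", "eye", NULL),
              list("MA:0000262", "posterior eye", "MA:0000261")),
    FMA = list(list("FMA:54448", "eye", NULL),
               list("FMA:9670", "portion of blood", NULL)))
  for (prefix in c("ZFA", "MA", "FMA")) {
    st <- tree_stanzas(prefix, 100000L, a_labels, a_parent)
    if (fig) {
      root <- fx_id(prefix, 100001L)
      for (ex in species_extra[[prefix]])
        st <- c(st, list(obo_stanza(ex[[1]], name = ex[[2]],
                                    is_a = ex[[3]] %||% root)))
    }
    write_obo(obo_document(st, c("format-version" = "1.2",
                                 ontology = tolower(prefix))),
              p(paste0(tolower(prefix), ".obo")))
  }

  n_bridged <- round(spec$bridge_fraction * ne)
  bridged <- sort(sample(seq_len(ne), n_bridged))
  ub <- lapply(seq_len(ne), function(i) {
    obo_stanza(fx_id("UBERON", 100000L + i), name = a_labels[i],
               is_a = if (is.na(a_parent[i])) character()
                      else fx_id("UBERON", 100000L + a_parent[i]),
               xrefs = if (i %in% bridged && i > 1L)
                 c(fx_id("ZFA", 100000L + i), fx_id("MA", 100000L + i),
                   fx_id("FMA", 100000L + i)) else character(),
               # the root is a very general term: cross-referenced but
               # excluded from bridging through the upper_level subset
               subsets = if (i == 1L) "upper_level" else character())
  })
  ub[[1]]$xrefs <- c(fx_id("ZFA", 100001L), fx_id("MA", 100001L),
                     fx_id("FMA", 100001L))
  if (fig) {
    uroot <- fx_id("UBERON", 100001L)
    ub <- c(ub, list(
      obo_stanza("UBERON:0000970", name = "eye", is_a = uroot,
                 xrefs = c("ZFA:0000107", "MA:0000261", "FMA:54448")),
      obo_stanza("UBERON:0002110", name = "gall bladder", is_a = uroot,
                 xrefs = "ZFA:0000208"),
      obo_stanza("UBERON:0000178", name = "blood", is_a = uroot,
                 xrefs = "FMA:9670")))
  }
  write_obo(obo_document(ub, c("format-version" = "1.2", ontology = "uberon")),
            p("uberon.obo"))

  ## GO and its anatomy cross-products -------------------------------------
  go <- list(obo_stanza("GO:0008150", name = "biological_process"),
             obo_stanza("GO:0043473", name = "pigmentation",
                        is_a = "GO:0008150"),
             obo_stanza("GO:0048069", name = "eye pigmentation"))
  write_obo(obo_document(go, c("format-version" = "1.2", ontology = "go")),
            p("go.obo"))
  go_xp <- if (fig) list(obo_stanza(
    "GO:0048069", name = "eye pigmentation",
    intersection_of = data.frame(
      relation = c(NA, "occurs_in"),
      target = c("GO:0043473", "UBERON:0000970"), stringsAsFactors = FALSE)))
  else list()
  write_obo(obo_document(go_xp, c("format-version" = "1.2", ontology = "go_xp")),
            p("go-xp.obo"))

  ## phenotype ontologies and their logical definitions --------------------
  npc <- spec$n_pheno_classes
  q_pool <- fx_id("PATO", 200000L + seq_len(nq))
  combos <- expand.grid(q = seq_len(nq), e = seq_len(ne))
  combos <- combos[sample(nrow(combos), npc + 1L), , drop = FALSE]
  chem_pool <- fx_id("CHEBI", 100001L + seq_len(n_chem))

  make_pheno <- function(prefix, base, entity_prefix, label_word) {
    ids <- fx_id(prefix, base + seq_len(npc))
    undefined <- stats::runif(npc) < 0.2
    if (npc >= 4L && !any(undefined)) undefined[npc] <- TRUE
    stanzas <- list(); defs <- list()
    for (i in seq_len(npc)) {
      parents <- character()
      und <- which(undefined[seq_len(npc)])
      und <- und[und != i]
      if (!undefined[i] && length(und) && stats::runif(1) < 0.5)
        parents <- ids[if (length(und) == 1L) und else sample(und, 1L)]
      stanzas[[i]] <- obo_stanza(ids[i],
                                 name = paste(label_word, "phenotype", i),
                                 is_a = parents)
      if (!undefined[i]) {
        qi <- q_pool[combos$q[i]]
        ei <- fx_id(entity_prefix, 100000L + combos$e[i])
        io <- data.frame(relation = NA_character_, target = qi,
                         stringsAsFactors = FALSE)
        io[2, ] <- list("inheres_in", ei)
        if (stats::runif(1) < 0.25)
          io[nrow(io) + 1L, ] <- list("towards", sample(chem_pool, 1L))
        if (stats::runif(1) < 0.5)   # the rest rely on qualifier normalization
          io[nrow(io) + 1L, ] <- list("qualifier", "PATO:0000460")
        defs[[ids[i]]] <- obo_stanza(ids[i], intersection_of = io)
      }
    }
    list(stanzas = stanzas, defs = defs)
  }
  hp <- make_pheno("HP", 210000L, "UBERON", "HP")
  mp <- make_pheno("MP", 220000L, "MA", "MP")

  if (fig) {
    xp <- function(id, quality, bearer = NA, towards = NA, qualifier = NA) {
      io <- data.frame(relation = NA_character_, target = quality,
                       stringsAsFactors = FALSE)
      if (!is.na(bearer)) io[nrow(io) + 1L, ] <- list("inheres_in", bearer)
      if (!is.na(towards)) io[nrow(io) + 1L, ] <- list("towards", towards)
      if (!is.na(qualifier)) io[nrow(io) + 1L, ] <- list("qualifier", qualifier)
      obo_stanza(id, intersection_of = io)
    }
    hp$stanzas <- c(hp$stanzas, list(
      obo_stanza("HP:0001943", name = "Hypoglycemia"),
      obo_stanza("HP:0040001", name = "Decreased aldohexose concentration (blood)"),
      obo_stanza("HP:0007633", name = "Bilateral microphthalmos"),
      obo_stanza("HP:0005609", name = "Gallbladder dysfunction"),
      obo_stanza("HP:0001288", name = "Abnormal gait"),
      obo_stanza("HP:0107001", name = "Abnormal pigmentation")))
    hp$defs <- c(hp$defs, list(
      `HP:0001943` = xp("HP:0001943", "PATO:0001163", "FMA:9670",
                        "CHEBI:17234", "PATO:0000460"),
      `HP:0040001` = xp("HP:0040001", "PATO:0001163", "FMA:9670",
                        "CHEBI:33917"),
      `HP:0007633` = xp("HP:0007633", "PATO:0000587", "UBERON:0000970",
                        qualifier = "PATO:0000460"),
      `HP:0005609` = xp("HP:0005609", "PATO:0001641", "UBERON:0002110",
                        qualifier = "PATO:0000460"),
      `HP:0107001` = xp("HP:0107001", "PATO:0000014", "GO:0043473",
                        qualifier = "PATO:0000460")))
    mp$stanzas <- c(mp$stanzas, list(
      obo_stanza("MP:0011234", name = "posterior microphthalmia"),
      obo_stanza("MP:0001406", name = "abnormal gait"),
      obo_stanza("MP:0107002", name = "abnormal eye pigmentation")))
    mp$defs <- c(mp$defs, list(
      `MP:0011234` = xp("MP:0011234", "PATO:0000645", "MA:0000262",
                        qualifier = "PATO:0000460"),
      `MP:0107002` = xp("MP:0107002", "PATO:0000014", "GO:0048069",
                        qualifier = "PATO:0000460")))
  }
  write_obo(obo_document(hp$stanzas, c("format-version" = "1.2", ontology = "hp")),
            p("hp.obo"))
  write_obo(obo_document(mp$stanzas, c("format-version" = "1.2", ontology = "mp")),
            p("mp.obo"))
  write_obo(obo_document(unname(hp$defs),
                         c("format-version" = "1.2", ontology = "hp_xp")),
            p("hp-xp.obo"))
  write_obo(obo_document(unname(mp$defs),
                         c("format-version" = "1.2", ontology = "mp_xp")),
            p("mp-xp.obo"))

  ## post-composed zebrafish phenotype file --------------------------------
  zgenes <- sprintf("ZDB-GENE-000000-%d", seq_len(spec$n_genes))
  zsyms <- sprintf("zgene%d", seq_len(spec$n_genes))
  zentrez <- 20000L + seq_len(spec$n_genes)
  n_lines <- max(2L * spec$n_genes, npc)
  lines <- character(n_lines)
  anat_label <- function(e) a_labels[e]
  qual_label <- function(q) q_labels[q]
  for (i in seq_len(n_lines)) {
    g <- ((i - 1L) %% spec$n_genes) + 1L
    cmb <- if (i <= npc) i else sample(npc, 1L)
    lines[i] <- paste(zgenes[g], zentrez[g], zsyms[g],
                      fx_id("ZFA", 100000L + combos$e[cmb]),
                      anat_label(combos$e[cmb]),
                      q_pool[combos$q[cmb]],
                      qual_label(combos$q[cmb]),
                      "abnormal", sep = "\t")
  }
  # a "normal"-modifier line with a fresh combination: dropped, no class
  lines <- c(lines, paste(zgenes[1], zentrez[1], zsyms[1],
                          fx_id("ZFA", 100000L + combos$e[npc + 1L]),
                          anat_label(combos$e[npc + 1L]),
                          q_pool[combos$q[npc + 1L]],
                          qual_label(combos$q[npc + 1L]),
                          "normal", sep = "\t"))
  if (fig) {
    lines <- c(lines,
      "ZDB-GENE-980605-30\t83439\ttcf7l1a\tZFA:0000107\teye\tPATO:0000645\thypoplastic\tabnormal",
      "ZDB-GENE-990415-8\t20990\tzgb1\tZFA:0000208\tgall bladder\tPATO:0001641\tdecreased functionality\tabnormal")
  }
  writeLines(lines, p("pheno.txt"))
  if (fig) {
    writeLines("PATO:0000645|ZFA:0000107\tZP:0003395", p("zp-idmap.tsv"))
  } else writeLines(character(), p("zp-idmap.tsv"))

  ## orthology tables -------------------------------------------------------
  zo <- sprintf("%s\t%s\t%s\t%d", zgenes, zsyms, toupper(zsyms), zentrez)
  if (fig) zo <- c(zo, "ZDB-GENE-980605-30\ttcf7l1a\tTCF7L1\t83439",
                   "ZDB-GENE-990415-8\tzgb1\tZGB1H\t20990")
  writeLines(zo, p("ortho.txt"))

  mgenes <- sprintf("MGI:%07d", 90000L + seq_len(spec$n_genes))
  msyms <- sprintf("Mgene%d", seq_len(spec$n_genes))
  mentrez <- 30000L + seq_len(spec$n_genes)
  mo <- sprintf("%s\t%d\t%s\t%s", toupper(msyms), mentrez, msyms, mgenes)
  if (fig) mo <- c(mo, "PRSS56\t646960\tPrss56\tMGI:3045960")
  writeLines(mo, p("HMD_HumanPhenotype.rpt"))

  mp_ids <- vapply(mp$stanzas, `[[`, character(1), "id")
  mp_random <- grep("^MP:022", mp_ids, value = TRUE)
  if (!length(mp_random)) mp_random <- mp_ids
  mpl <- character()
  for (g in seq_len(spec$n_genes)) {
    k <- sample(length(mp_random), 1L)
    for (t in sample(mp_random, k))
      mpl <- c(mpl, sprintf("%s<tm1>/%s<+>\t%s<tm1>\tC57BL/6\t%s\t12345\t%s",
                            msyms[g], msyms[g], msyms[g], t, mgenes[g]))
  }
  # one multi-marker genotype line
  if (spec$n_genes >= 2L && length(mp_random))
    mpl <- c(mpl, sprintf("%s<tm1> %s<tm1>\tdouble\tC57BL/6\t%s\t12345\t%s,%s",
                          msyms[1], msyms[2], mp_random[1], mgenes[1], mgenes[2]))
  if (fig)
    mpl <- c(mpl, "Prss56<tm1>/Prss56<tm1>\tPrss56<tm1>\tC57BL/6\tMP:0011234\t12345\tMGI:3045960")
  writeLines(mpl, p("MGI_PhenoGenoMP.rpt"))

  ## human disease data ------------------------------------------------------
  hp_ids <- vapply(hp$stanzas, `[[`, character(1), "id")
  n_dis <- max(2L, spec$n_genes %/% 2L)
  dis_id <- 610000L + seq_len(n_dis)
  dis_gene_entrez <- 40000L + seq_len(n_dis)
  dis_gene_sym <- sprintf("HGENE%d", seq_len(n_dis))
  pa <- character(); m2g <- character()
  first_hp <- character(n_dis)
  for (d in seq_len(n_dis)) {
    terms <- sample(hp_ids, sample(1:3, 1L))
    first_hp[d] <- terms[1]
    pa <- c(pa, sprintf("OMIM\t%d\ttoy disease %d\t\t%s", dis_id[d], d, terms))
    m2g <- c(m2g, sprintf("%d\t%d\t%s", dis_id[d], dis_gene_entrez[d],
                          dis_gene_sym[d]))
  }
  # an Orphanet disease sharing a (gene, term) pair with an OMIM disease:
  # the merged record carries evidence from both databases
  pa <- c(pa, sprintf("ORPHA\t7001\ttoy orpha disease\t\t%s", first_hp[1]))
  orpha <- sprintf("7001\t%s", dis_gene_sym[1])
  if (fig) {
    pa <- c(pa, "OMIM\t610199\tisolated microphthalmia\t\tHP:0007633")
    m2g <- c(m2g, "610199\t6949\tTCOF1")
  }
  writeLines(pa, p("phenotype_annotation.tab"))
  writeLines(m2g, p("mim2gene.txt"))
  writeLines(orpha, p("orphanet_genes.tsv"))

  ## config ------------------------------------------------------------------
  cfg <- list(pato = "pato.obo", chebi = "chebi.obo", go = "go.obo",
              go_xp = "go-xp.obo", fma = "fma.obo", ma = "ma.obo",
              zfa = "zfa.obo", uberon = "uberon.obo", hp = "hp.obo",
              mp = "mp.obo", hp_xp = "hp-xp.obo", mp_xp = "mp-xp.obo",
              pheno_txt = "pheno.txt", zp_idmap = "zp-idmap.tsv",
              mouse_ortho = "HMD_HumanPhenotype.rpt",
              zfin_ortho = "ortho.txt",
              mouse_pheno = "MGI_PhenoGenoMP.rpt",
              disease_pheno = "phenotype_annotation.tab",
              omim_gene_map = "mim2gene.txt",
              orphanet_gene_map = "orphanet_genes.tsv",
              entity_mode = "is_a_only",
              lexical_align = TRUE,
              bridge_prefixes = c("ZFA", "MA", "FMA"),
              out_dir = "build")
  yaml::write_yaml(cfg, p("config.yaml"))
  invisible(list(dir = dir, config = p("config.yaml"),
                 files = stats::setNames(file.path(dir, unlist(cfg[1:20])),
                                         names(cfg)[1:20])))
}
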