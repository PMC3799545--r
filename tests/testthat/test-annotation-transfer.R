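# a minimal merged-cluster object for id resolution
toy_merged <- function(groups) {
  ids <- sort(unlist(groups))
  M <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  diag(M) <- TRUE
  for (g in groups) for (a in g) for (b in g) M[a, b] <- TRUE
  res <- structure(list(classes = ids, matrix = M,
                        equivalence_groups = lapply(groups, sort)),
                   class = "subsumption_result")
  merge_clusters(res)
}

test_that("orthology tables load, deduplicate and report bad lines", {
  mouse <- c("PRSS56\t646960\tPrss56\tMGI:3045960",
             "PRSS56\t646960\tPrss56\tMGI:3045960",
             "short\tline")
  zfin <- c("ZDB-GENE-980605-30\ttcf7l1a\tTCF7L1\t83439",
            "ZDB-GENE-000000-1\tzgene1\tZGENE1\tnotanumber")
  om <- load_orthology(mouse, zfin)
  expect_equal(nrow(om$mouse), 1L)
  expect_equal(om$mouse$human_entrez, 646960L)
  expect_equal(om$zebrafish$model_id, "ZDB-GENE-980605-30")
  expect_equal(om$zebrafish$human_entrez, 83439L)
  expect_equal(nrow(om$report), 2L)
  empty <- load_orthology(character(), character())
  expect_equal(nrow(empty$mouse) + nrow(empty$zebrafish), 0L)
})

test_that("disease joins produce one record per (gene, term) with merged evidence", {
  dp <- c("OMIM\t600001\ttoy disease\t\tHP:0000001",
          "OMIM\t600001\ttoy disease\t\tHP:0000002",
          "ORPHA\t7001\torpha disease\t\tHP:0000001",
          "OMIM\t600002\tno gene disease\t\tHP:0000003")
  omim <- "600001\t100\tGENEA"
  orpha <- "7001\tGENEA"
  h <- human_gene_annotations(dp, omim, orpha)
  expect_equal(nrow(h$records), 2L)
  r1 <- h$records[h$records$pheno_class == "HP:0000001", ]
  expect_equal(r1$evidence, "OMIM,Orphanet")
  r2 <- h$records[h$records$pheno_class == "HP:0000002", ]
  expect_equal(r2$evidence, "OMIM")
  expect_equal(unname(h$report["diseases_without_gene"]), 1L)
  expect_true(all(h$records$source_species == "human"))
})

test_that("record count equals the brute-force join on randomized inputs", {
  set.seed(81)
  for (i in 1:20) {
    nd <- sample(2:5, 1)
    dis <- 600000 + seq_len(nd)
    dp <- sprintf("OMIM\t%d\tdis\t\tHP:%07d", sample(dis, 12, TRUE),
                  sample(4, 12, TRUE))
    omim <- sprintf("%d\t%d\tG%d", dis, 100 + seq_len(nd) %% 3, 100 + seq_len(nd) %% 3)
    h <- human_gene_annotations(dp, omim)
    # oracle: unique (gene, term) pairs over an explicit double loop
    f <- do.call(rbind, strsplit(dp, "\t"))
    g <- do.call(rbind, strsplit(omim, "\t"))
    pairs <- character()
    for (a in seq_len(nrow(f))) for (b in seq_len(nrow(g)))
      if (f[a, 2] == g[b, 1]) pairs <- c(pairs, paste(g[b, 2], f[a, 5]))
    expect_equal(nrow(h$records), length(unique(pairs)))
  }
})

test_that("genotype-level mouse annotations fan out to each involved marker", {
  lines <- c("G<tm1>/G<tm1>\tG<tm1>\tB6\tMP:0000001\t111\tMGI:0000001",
             "G<tm1> H<tm2>\tdouble\tB6\tMP:0000002\t111\tMGI:0000001,MGI:0000002")
  res <- parse_mouse_pheno(lines)
  expect_equal(nrow(res$annotations), 3L)
  expect_setequal(res$annotations$model_id[res$annotations$pheno == "MP:0000002"],
                  c("MGI:0000001", "MGI:0000002"))
})

test_that("model annotations transfer over orthology with primary-id rewrite", {
  merged <- toy_merged(list(c("HP:0005609", "ZP:0004170"), "MP:0000001",
                            "ZP:0000001"))
  ortho <- load_orthology("GENEM\t300\tGenem\tMGI:0000001",
                          c("ZDB-GENE-1\tzg1\tZG1\t200",
                            "ZDB-GENE-2\tzg2\tZG2\t201"))
  zp_annots <- data.frame(gene_id = c("ZDB-GENE-1", "ZDB-GENE-2", "ZDB-GENE-9"),
                          symbol = c("zg1", "zg2", "zg9"),
                          zp_id = c("ZP:0004170", "ZP:0000001", "ZP:0000001"),
                          stringsAsFactors = FALSE)
  mouse <- data.frame(model_id = "MGI:0000001",
                      pheno = c("MP:0000001", "MP:0009999"),
                      stringsAsFactors = FALSE)
  tr <- transfer_model_annotations(mouse, zp_annots, ortho, merged)
  # the ZP id that merged into an HP cluster is rewritten to the HP primary
  z1 <- tr$records[tr$records$source_gene_id == "ZDB-GENE-1", ]
  expect_equal(z1$pheno_class, "HP:0005609")
  expect_equal(z1$human_entrez, 200L)
  # gene without ortholog drops its annotation; unknown pheno id reported
  expect_equal(unname(tr$report$no_ortholog["zebrafish"]), 1L)
  expect_equal(tr$report$unresolved_pheno_ids, "MP:0009999")
  expect_setequal(tr$records$source_species, c("mouse", "zebrafish"))
})

test_that("no ortholog means no records at all", {
  merged <- toy_merged(list("ZP:0000001"))
  ortho <- load_orthology(character(), character())
  zp_annots <- data.frame(gene_id = "ZDB-GENE-1", symbol = "zg1",
                          zp_id = "ZP:0000001", stringsAsFactors = FALSE)
  tr <- transfer_model_annotations(NULL, zp_annots, ortho, merged)
  expect_equal(nrow(tr$records), 0L)
})

test_that("the worked-example output row is rendered token for token", {
  merged <- toy_merged(list("ZP:0003395"))
  ortho <- load_orthology(character(),
                          "ZDB-GENE-980605-30\ttcf7l1a\tTCF7L1\t83439")
  zp_annots <- data.frame(gene_id = "ZDB-GENE-980605-30", symbol = "tcf7l1a",
                          zp_id = "ZP:0003395", stringsAsFactors = FALSE)
  tr <- transfer_model_annotations(NULL, zp_annots, ortho, merged)
  lines <- write_hs_annotations(tr$records,
                                c(`ZP:0003395` = "abnormal(ly) hypoplastic eye"))
  expect_identical(
    lines,
    "83439\tTCF7L1\tabnormal(ly) hypoplastic eye (ZP:0003395)\ttcf7l1a (ZDB-GENE-980605-30/ZEBRAF)")
})

test_that("transfer is idempotent and partitions by source species", {
  fx <- fig_pipeline()
  rec <- fx$res$records
  expect_equal(nrow(rec),
               sum(rec$source_species == "human") +
                 sum(rec$source_species == "mouse") +
                 sum(rec$source_species == "zebrafish"))
  expect_equal(anyDuplicated(rec[, c("human_entrez", "pheno_class",
                                     "source_species", "source_gene_id")]), 0L)
  # rerunning the transfer on identical inputs changes nothing
  ortho <- load_orthology(fx$fx$files[["mouse_ortho"]],
                          fx$fx$files[["zfin_ortho"]])
  tr1 <- transfer_model_annotations(NULL, fx$res$zp$annotations, ortho,
                                    fx$res$merged)
  tr2 <- transfer_model_annotations(NULL, fx$res$zp$annotations, ortho,
                                    fx$res$merged)
  expect_identical(tr1$records, tr2$records)
})

test_that("phenotype queries resolve alt_ids and include descendants", {
  fx <- fig_pipeline()
  g <- genes_for_phenotype(fx$res$records, fx$res$export_doc, "HP:0007633")
  expect_setequal(g$human_symbol[g$source_species == "zebrafish"], "TCF7L1")
  expect_setequal(g$human_symbol[g$source_species == "mouse"], "PRSS56")
  expect_true("TCOF1" %in% g$human_symbol[g$source_species == "human"])
  direct <- genes_for_phenotype(fx$res$records, fx$res$export_doc,
                                "HP:0007633", include_descendants = FALSE)
  expect_false("TCF7L1" %in% direct$human_symbol)
  expect_error(genes_for_phenotype(fx$res$records, fx$res$export_doc,
                                   "HP:1111111"), "unknown")
})
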