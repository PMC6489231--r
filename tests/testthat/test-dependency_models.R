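# Feature assembly, model fitting, permutation calibration, summaries.

test_that("assemble_features has the expected columns and categories", {
  ds <- manual_dataset(n_lines = 30, genes = c("gA", "gB", "gC", "gD"),
                       oncogenes = sprintf("onc%d", 1:5),
                       medium = rep(c("DMEM", "RPMI", "McCoy"), 10))
  rel <- manual_relatedness(neighbors = list(gA = c("gB", "gC")),
                            isozymes = list(gA = "gD"))
  ft <- assemble_features("gA", ds, rel, include_lineage = FALSE)
  # 2 self + 2 iso + 4 neighbor + 5 mutations + 3 media = 16 (none constant)
  expect_equal(ncol(ft$matrix), 16L)
  expect_equal(unname(ft$categories[c("self_exp", "iso_exp.gD", "rel_exp.gB",
                                      "mut.onc1", "media.DMEM")]),
               c("self_exp", "iso_exp", "related_exp", "mutation", "media"))
  expect_identical(rownames(ft$matrix), ds$cell_lines)

  # all lines in one medium -> media columns dropped as constant
  ds1 <- manual_dataset(n_lines = 30, genes = c("gA", "gB"),
                        medium = rep("DMEM", 30))
  expect_message(
    ft1 <- assemble_features("gA", ds1, manual_relatedness(),
                             include_lineage = FALSE),
    "constant"
  )
  expect_false(any(grepl("^media", colnames(ft1$matrix))))
  expect_true("media.DMEM" %in% ft1$dropped)
})

test_that("lineage one-hots pool small lineages into other", {
  ds <- manual_dataset(n_lines = 40,
                       lineage = c(rep("big1", 20), rep("big2", 15),
                                   rep("tiny", 5)))
  ft <- assemble_features("gA", ds, manual_relatedness(),
                          include_lineage = TRUE, min_lineage = 10)
  lin_cols <- grep("^lineage", colnames(ft$matrix), value = TRUE)
  expect_setequal(lin_cols, c("lineage.big1", "lineage.big2", "lineage.other"))
})

test_that("a gene without relatedness proceeds with base features", {
  ds <- manual_dataset()
  expect_message(
    ft <- assemble_features("gA", ds, manual_relatedness(), include_lineage = FALSE),
    "absent from relatedness"
  )
  expect_true(all(ft$categories %in% c("self_exp", "self_cnv", "mutation",
                                       "media")))
})

test_that("missing feature values are mean-imputed", {
  ds <- manual_dataset(n_lines = 30)
  ds$expression["gA", 1:3] <- NA
  ft <- suppressMessages(assemble_features("gA", ds, manual_relatedness(),
                                           include_lineage = FALSE))
  v <- ft$matrix[, "self_exp"]
  expect_false(anyNA(v))
  expect_equal(unname(v[1]), mean(ds$expression["gA", ], na.rm = TRUE))
})

test_that("empirical significance matches hand counting", {
  models <- data.frame(gene = paste0("g", 1:4),
                       oob_p = c(0.001, 0.5, NA, 0.02),
                       unexplainable = c(FALSE, FALSE, FALSE, FALSE))
  null_ps <- c(0.005, 0.01, 0.05, seq(0.1, 1, length.out = 96))
  out <- empirical_significance(models, null_ps, alpha = 0.05)
  expect_equal(out$empirical_p[1], 1 / 100)        # below all 99 nulls
  # nulls <= 0.5: the 3 small ones + 43 grid points (0.1 + k*0.9/95 <= 0.5)
  expect_equal(out$empirical_p[2], (1 + 46) / 100)
  expect_true(is.na(out$empirical_p[3]))
  expect_equal(out$empirical_p[4], (1 + 2) / 100)
  expect_equal(out$fdr_p, bh_fdr(out$empirical_p))
  # observed at or above every null -> empirical p = 1
  one <- empirical_significance(data.frame(gene = "g", oob_p = 1,
                                           unexplainable = FALSE), null_ps)
  expect_equal(one$empirical_p, 1)
})

test_that("fit_dependency_models recovers a planted coupling end to end", {
  cfg0 <- synthetic_config(n_reactions = 25, n_genes_metabolic = 15,
                           n_genes_other = 20, n_cell_lines = 150,
                           n_oncogenes = 8, seed = 31)
  gm <- generate_model(cfg0)
  target <- names(Filter(length, gm$truth$neighbors))[1]
  partner <- gm$truth$neighbors[[target]][1]
  cfg <- synthetic_config(n_reactions = 25, n_genes_metabolic = 15,
                          n_genes_other = 20, n_cell_lines = 150,
                          n_oncogenes = 8, seed = 31,
                          planted_effects = list(planted_effect(
                            "neighbor_expression", target, effect_size = 1.5,
                            partner = partner)))
  scr <- generate_screen(cfg, gm$model, gm$truth)
  rel <- manual_relatedness(neighbors = gm$truth$neighbors,
                            isozymes = gm$truth$isozymes)
  genes <- c(target, setdiff(scr$dataset$metabolic_genes, target)[1:4])
  models <- suppressMessages(fit_dependency_models(
    scr$dataset, rel, genes = genes, seed = 5))
  expect_equal(nrow(models), 5L)
  # 120 repetitions: the smallest attainable empirical p is 1/121, which
  # after BH across 5 genes still clears 0.05
  null_ps <- permutation_null(scr$dataset, rel, genes = genes,
                              repetitions = 120, seed = 6)
  expect_length(null_ps, 120)
  out <- empirical_significance(models, null_ps)
  hit <- out[out$gene == target, ]
  expect_true(hit$significant)
  expect_match(hit$top5, paste0("rel_exp\\.", partner))
  imps <- attr(models, "importances")[[target]]
  expect_true(paste0("rel_exp.", partner) %in% imps$feature[1:3])
})

test_that("permutation null is reproducible and roughly uniform on null data", {
  cfg <- synthetic_config(n_reactions = 20, n_genes_metabolic = 10,
                          n_genes_other = 10, n_cell_lines = 100,
                          n_oncogenes = 5, seed = 37)
  gm <- generate_model(cfg)
  scr <- generate_screen(cfg, gm$model, gm$truth)
  rel <- manual_relatedness(neighbors = gm$truth$neighbors,
                            isozymes = gm$truth$isozymes)
  genes <- scr$dataset$metabolic_genes[1:4]
  a <- permutation_null(scr$dataset, rel, genes, repetitions = 40, seed = 3)
  b <- permutation_null(scr$dataset, rel, genes, repetitions = 40, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a, permutation_null(scr$dataset, rel, genes,
                                             repetitions = 40, seed = 4)))
  expect_true(all(a >= 0 & a <= 1))
  expect_identical(a, sort(a))
})

test_that("categorize_top_features summarizes fractions", {
  models <- data.frame(
    gene = paste0("g", 1:4),
    significant = c(TRUE, TRUE, TRUE, FALSE),
    top_feature = c("rel_exp.x", "rel_exp.y", "mut.onc1", "self_exp"),
    top_category = c("related_exp", "related_exp", "mutation", "self_exp"),
    top5 = c("rel_exp.x|related_exp;self_exp|self_exp",
             "rel_exp.y|related_exp;mut.onc1|mutation",
             "mut.onc1|mutation;media.DMEM|media",
             "self_exp|self_exp"),
    stringsAsFactors = FALSE)
  out <- categorize_top_features(models)
  cats <- out$categories
  expect_equal(cats$fraction_top[cats$category == "related_exp"], 2 / 3)
  expect_equal(cats$fraction_top5[cats$category == "mutation"], 2 / 3)
  expect_equal(cats$fraction_top5[cats$category == "media"], 1 / 3)
  expect_equal(out$features$fraction_top5[out$features$category == "mut.onc1"],
               2 / 3)
  # all models topped by one category -> fraction 1
  m2 <- models[1:2, ]
  expect_equal(categorize_top_features(m2)$categories$fraction_top[
    categorize_top_features(m2)$categories$category == "related_exp"], 1)
  # empty input -> empty summary
  empty <- categorize_top_features(models[0, ])
  expect_equal(nrow(empty$categories), 0L)
})

test_that("shuffled_related_control is reproducible at fixed seed", {
  cfg <- synthetic_config(n_reactions = 20, n_genes_metabolic = 10,
                          n_genes_other = 10, n_cell_lines = 100,
                          n_oncogenes = 4, seed = 41)
  gm <- generate_model(cfg)
  scr <- generate_screen(cfg, gm$model, gm$truth)
  rel <- manual_relatedness(neighbors = gm$truth$neighbors,
                            isozymes = gm$truth$isozymes)
  genes <- scr$dataset$metabolic_genes[1:3]
  null_ps <- permutation_null(scr$dataset, rel, genes, repetitions = 30,
                              seed = 2)
  a <- shuffled_related_control(scr$dataset, rel, genes, null_ps,
                                repetitions = 2, seed = 8)
  b <- shuffled_related_control(scr$dataset, rel, genes, null_ps,
                                repetitions = 2, seed = 8)
  expect_identical(a, b)
  expect_length(a$control_fractions, 2)
})
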