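# Media associations, confounder controls, related-expression analyses.

planted_media_screen <- function(seed, effect = 2, n_lines = 120,
                                 extra_effects = list()) {
  cfg <- synthetic_config(
    n_reactions = 25, n_genes_metabolic = 15, n_genes_other = 30,
    n_cell_lines = n_lines, n_oncogenes = 5, seed = seed,
    planted_effects = c(list(planted_effect("media_shift", "MG0001",
                                            effect_size = effect,
                                            medium = "DMEM")),
                        extra_effects))
  gm <- generate_model(cfg)
  list(cfg = cfg, gm = gm, scr = generate_screen(cfg, gm$model, gm$truth))
}

test_that("a planted media shift is detected with the right direction", {
  s <- planted_media_screen(1)
  res <- media_association(s$scr$dataset, s$scr$dataset$metabolic_genes,
                           "DMEM", "RPMI")
  hit <- res[res$gene == "MG0001", ]
  expect_lt(hit$fdr_p, 0.05)
  expect_equal(hit$direction, -1)  # more essential (lower) in DMEM
  # null genes are not called
  others <- res[res$gene != "MG0001", ]
  expect_gt(min(others$fdr_p), 0.05)
})

test_that("media_association validates labels and flags short groups", {
  s <- planted_media_screen(2)
  expect_error(media_association(s$scr$dataset, "MG0001", "DMEM", "broth"),
               "unknown medium")
})

test_that("permuted media labels yield ~no discoveries", {
  s <- planted_media_screen(3)
  ds <- s$scr$dataset
  set.seed(42)
  ds$annotations$medium <- sample(ds$annotations$medium)
  res <- media_association(ds, ds$metabolic_genes, "DMEM", "RPMI")
  expect_lte(mean(res$fdr_p < 0.05, na.rm = TRUE), 0.05)
})

test_that("culture-type partial correlation survives a genuine media effect", {
  s <- planted_media_screen(4, effect = 2.5)
  pr <- media_partial_association(s$scr$dataset, s$scr$dataset$metabolic_genes,
                                  "DMEM", "RPMI", control = "culture_type")
  expect_lt(pr$fdr_p[pr$gene == "MG0001"], 0.05)
  expect_equal(pr$test[1], "partial_media_culture")
})

test_that("lineage robustness separates media-driven from lineage-confounded", {
  # genuinely media-driven gene: orthogonal to lineage
  s <- planted_media_screen(5, effect = 2.5)
  rob <- lineage_robustness(s$scr$dataset, s$scr$dataset$metabolic_genes,
                            "DMEM", "RPMI")
  expect_true(rob[["MG0001"]])

  # confounded gene: one lineage drives both medium assignment and the shift
  cfg <- synthetic_config(
    n_reactions = 25, n_genes_metabolic = 15, n_genes_other = 30,
    n_cell_lines = 150, n_oncogenes = 5, seed = 6,
    media_culture_confounding = 0.2,
    lineage_media_bias = list(lineage = 1, medium = "DMEM", strength = 0.95),
    planted_effects = list(planted_effect("lineage_shift", "MG0002",
                                          effect_size = 2.5, lineage = 1)))
  gm <- generate_model(cfg)
  scr <- generate_screen(cfg, gm$model, gm$truth)
  rob2 <- lineage_robustness(scr$dataset, scr$dataset$metabolic_genes,
                             "DMEM", "RPMI")
  expect_false(rob2[["MG0002"]])
})

test_that("single-lineage datasets fall back to the unadjusted test", {
  ds <- manual_dataset(n_lines = 40, lineage = rep("only", 40))
  expect_message(
    rob <- lineage_robustness(ds, "gA", "DMEM", "RPMI"),
    "falling back"
  )
  expect_type(rob, "logical")
})

test_that("no qualifying lineage returns vacuous TRUE with a message", {
  ds <- manual_dataset(n_lines = 18,
                       lineage = rep(sprintf("l%d", 1:6), each = 3))
  expect_message(
    rob <- lineage_robustness(ds, "gA", "DMEM", "RPMI", min_lines = 10),
    "vacuously"
  )
  expect_true(all(rob))
})

test_that("planted neighbor coupling marks the gene as explained, negative", {
  cfg0 <- synthetic_config(n_reactions = 25, n_genes_metabolic = 15,
                           n_genes_other = 30, n_cell_lines = 120,
                           n_oncogenes = 5, seed = 7)
  gm <- generate_model(cfg0)
  target <- names(Filter(length, gm$truth$neighbors))[1]
  partner <- gm$truth$neighbors[[target]][1]
  cfg <- synthetic_config(n_reactions = 25, n_genes_metabolic = 15,
                          n_genes_other = 30, n_cell_lines = 120,
                          n_oncogenes = 5, seed = 7,
                          planted_effects = list(planted_effect(
                            "neighbor_expression", target, effect_size = 1.5,
                            partner = partner)))
  scr <- generate_screen(cfg, gm$model, gm$truth)
  rel <- manual_relatedness(neighbors = gm$truth$neighbors,
                            isozymes = gm$truth$isozymes)
  res <- related_expression_correlations(scr$dataset, rel, "neighbor",
                                         genes = scr$dataset$metabolic_genes)
  expect_true(attr(res, "explained")[[target]])
  pair <- res[res$gene == target & res$partner == partner, ]
  expect_lt(pair$fdr_p, 0.05)
  expect_equal(pair$direction, -1)
})

test_that("self mode, empty maps and constant partners behave", {
  ds <- manual_dataset()
  self <- related_expression_correlations(ds, mode = "self", genes = "gA")
  expect_equal(nrow(self), 1L)
  expect_equal(self$partner, "gA")

  empty <- related_expression_correlations(ds, manual_relatedness(),
                                           "neighbor", genes = "gA")
  expect_equal(nrow(empty), 0L)

  ds$expression["gB", ] <- 3  # constant partner expression
  rel <- manual_relatedness(neighbors = list(gA = "gB"))
  skip <- related_expression_correlations(ds, rel, "neighbor", genes = "gA")
  expect_equal(nrow(skip), 0L)
})

test_that("shuffled-set null: formula boundaries and planted separation", {
  # planted coupling: observed fraction should beat random sets
  cfg0 <- synthetic_config(n_reactions = 25, n_genes_metabolic = 15,
                           n_genes_other = 100, n_cell_lines = 120,
                           n_oncogenes = 5, seed = 8)
  gm <- generate_model(cfg0)
  target <- names(Filter(length, gm$truth$neighbors))[1]
  partner <- gm$truth$neighbors[[target]][1]
  cfg <- synthetic_config(n_reactions = 25, n_genes_metabolic = 15,
                          n_genes_other = 100, n_cell_lines = 120,
                          n_oncogenes = 5, seed = 8,
                          planted_effects = list(planted_effect(
                            "neighbor_expression", target, effect_size = 2,
                            partner = partner)))
  scr <- generate_screen(cfg, gm$model, gm$truth)
  rel <- manual_relatedness(neighbors = gm$truth$neighbors,
                            isozymes = gm$truth$isozymes)
  nul <- shuffled_set_null(scr$dataset, rel, "neighbor", repetitions = 19,
                           genes = scr$dataset$metabolic_genes, seed = 1)
  expect_length(nul$null_fractions, 19)
  expect_gt(nul$observed_fraction, 0)
  expect_true(nul$empirical_p > 0 && nul$empirical_p <= 1)
  expect_equal(nul$empirical_p,
               (1 + sum(nul$null_fractions >= nul$observed_fraction)) / 20)

  # repetitions = 1, null >= observed -> empirical p = 1
  ds <- manual_dataset()
  rel1 <- manual_relatedness(neighbors = list(gA = "gB"))
  one <- shuffled_set_null(ds, rel1, "neighbor", repetitions = 1,
                           genes = "gA", seed = 2)
  if (one$null_fractions[1] >= one$observed_fraction) {
    expect_equal(one$empirical_p, 1)
  } else {
    expect_equal(one$empirical_p, 0.5)
  }
})

test_that("shuffled-set null is reproducible under a fixed seed", {
  ds <- manual_dataset(n_lines = 30, genes = c("gA", "gB", "gC", "gD"))
  rel <- manual_relatedness(neighbors = list(gA = c("gB", "gC"), gB = "gD"))
  a <- shuffled_set_null(ds, rel, "neighbor", repetitions = 10,
                         genes = c("gA", "gB"), seed = 9)
  b <- shuffled_set_null(ds, rel, "neighbor", repetitions = 10,
                         genes = c("gA", "gB"), seed = 9)
  expect_identical(a, b)
})
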