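# Currency metabolites, neighbor extraction, isozymes.

# n_rx reactions over dummy metabolites, with `target` planted into
# `n_target` of them.
participation_model <- function(n_rx, n_target) {
  mets <- data.frame(id = c("target", sprintf("x%03d", seq_len(n_rx + 1))),
                     compartment = "c")
  rx <- lapply(seq_len(n_rx), function(i) {
    subs <- sprintf("x%03d", i)
    prods <- sprintf("x%03d", i + 1)
    if (i <= n_target) prods <- c(prods, "target")
    metdep:::new_reaction(sprintf("R%04d", i),
                          data.frame(metabolite = subs, coef = 1),
                          data.frame(metabolite = prods, coef = 1),
                          FALSE, NULL)
  })
  metabolic_model(mets, rx)
}

test_that("currency threshold is a strict > on the reaction fraction", {
  # 250 reactions: 3 (1.2%) in, 2 (0.8%) out
  expect_true("target" %in%
    identify_currency_metabolites(participation_model(250, 3), 0.01))
  expect_false("target" %in%
    identify_currency_metabolites(participation_model(250, 2), 0.01))
  # exactly 1%: 2 of 200 reactions -> excluded
  expect_false("target" %in%
    identify_currency_metabolites(participation_model(200, 2), 0.01))
  # just above: 3 of 200 (1.5%) -> included
  expect_true("target" %in%
    identify_currency_metabolites(participation_model(200, 3), 0.01))
})

test_that("empty model errors; drop_exchange removes one-sided reactions", {
  expect_error(identify_currency_metabolites(
    metabolic_model(data.frame(id = "A", compartment = "c"), list()), 0.01),
    "no reactions")
  # exchange reaction (empty substrate side) inflates a metabolite's count:
  # with it, B is in 2 of 3 reactions (67% > 60%); without, 1 of 2 (50%)
  mets <- data.frame(id = c("A", "B", "C", "D"), compartment = "c")
  rx <- list(
    metdep:::new_reaction("R1", data.frame(metabolite = "A", coef = 1),
                          data.frame(metabolite = "B", coef = 1), FALSE, NULL),
    metdep:::new_reaction("R2", data.frame(metabolite = "C", coef = 1),
                          data.frame(metabolite = "D", coef = 1), FALSE, NULL),
    metdep:::new_reaction("EX1", NULL,
                          data.frame(metabolite = "B", coef = 1), TRUE, NULL))
  m <- metabolic_model(mets, rx)
  expect_true("B" %in% identify_currency_metabolites(m, 0.6))
  expect_false("B" %in% identify_currency_metabolites(m, 0.6,
                                                      drop_exchange = TRUE))
})

test_that("gene_reaction_membership includes every GPR leaf", {
  m <- ten_reaction_model()
  mem <- gene_reaction_membership(m)
  # AND members both map to the reaction
  expect_true(all(c("g2", "g3") %in%
                    names(Filter(function(v) "R03" %in% v, mem))))
  # full hand enumeration over the fixture
  expect_equal(mem$g2, c("R02", "R03", "R04"))
  expect_equal(mem$g5, c("R05", "R06"))
  expect_equal(mem$g10, "R09")
})

test_that("chain model neighbors follow shared non-currency metabolites", {
  m <- chain_model()
  nb <- extract_neighbors(m, currency = character(0), cap = 50)
  expect_equal(sort(nb$neighbors$g2), c("g1", "g3"))
  expect_equal(nb$neighbors$g1, "g2")
  # the connecting metabolite is recorded and non-currency
  expect_equal(unname(nb$connecting$g1["g2"]), "B")

  nb2 <- extract_neighbors(m, currency = "B", cap = 50)
  expect_equal(nb2$neighbors$g2, "g3")
  expect_equal(nb2$neighbors$g1, character(0))
})

test_that("cap keeps the lowest-degree connections, ties broken by gene id", {
  # hub metabolite "common" (high degree) connects g0 to every satellite;
  # distinct low-degree metabolites connect g0 to the first 6 satellites.
  n_sat <- 60
  sats <- sprintf("s%02d", seq_len(n_sat))
  mets <- data.frame(id = c("common", sprintf("lo%02d", 1:6),
                            sprintf("pad%02d", 1:n_sat)),
                     compartment = "c")
  rx <- list(metdep:::new_reaction("R0",
               data.frame(metabolite = "common", coef = 1),
               data.frame(metabolite = sprintf("lo%02d", 1:6), coef = rep(1, 6)),
               FALSE, parse_gpr("g0")))
  for (i in seq_len(n_sat)) {
    subs <- "common"
    if (i <= 6) subs <- c(subs, sprintf("lo%02d", i))
    rx[[i + 1]] <- metdep:::new_reaction(sprintf("R%02d", i),
      data.frame(metabolite = subs, coef = rep(1, length(subs))),
      data.frame(metabolite = sprintf("pad%02d", i), coef = 1),
      FALSE, parse_gpr(sats[i]))
  }
  m <- metabolic_model(mets, rx)
  nb <- extract_neighbors(m, currency = character(0), cap = 50,
                          exclude = character(0))
  got <- nb$neighbors$g0
  expect_length(got, 50)
  # the 6 low-degree connections rank first (degree 2), then hub-connected
  # satellites in lexicographic order (tie on the hub degree)
  expect_equal(got[1:6], sprintf("s%02d", 1:6))
  expect_equal(got[7:50], setdiff(sats, sprintf("s%02d", 1:6))[1:44])
  # oracle agreement on the whole structure
  expect_equal(nb$neighbors[order(names(nb$neighbors))],
               oracle_neighbors(m, character(0), 50)[
                 order(names(oracle_neighbors(m, character(0), 50)))])
})

test_that("excluded genes appear in no list and have no list", {
  m <- chain_model()
  nb <- extract_neighbors(m, currency = character(0), cap = 50,
                          exclude = "g2")
  expect_false("g2" %in% names(nb$neighbors))
  expect_false(any(vapply(nb$neighbors, function(v) "g2" %in% v, logical(1))))
  # default exclusion pattern catches EGFR/PIK-prefixed ids
  expect_equal(default_excluded_genes(c("EGFR", "PIK3CA", "PIKFYVE", "GCK")),
               c("EGFR", "PIK3CA", "PIKFYVE"))
})

test_that("isozymes are OR-alternatives, not complex partners", {
  m <- ten_reaction_model()
  iso <- identify_isozymes(m)
  expect_equal(iso$g1, c("g2", "g3", "g9"))     # R02, R04, R09
  expect_true("g3" %in% iso$g2)                  # (g1 and g2) or g3
  expect_false("g3" %in% setdiff(iso$g2, "g3") == FALSE && FALSE)
  expect_equal(iso$g3, c("g1", "g2"))
  expect_false("g2" %in% iso$g1[iso$g1 == "gX"])
  # pure AND pair are not isozymes: g2,g3 only related via R04 OR-branch
  expect_equal(iso$g5, c("g4", "g6", "g7"))      # R05 flat OR, R06 inner OR
  expect_false("g5" %in% iso$g10)
  expect_equal(iso$g8, character(0))
})

test_that("isozyme relation is symmetric, irreflexive, matches the oracle", {
  for (s in 1:10) {
    cfg <- synthetic_config(n_reactions = 20L, n_genes_metabolic = 12L,
                            seed = s)
    m <- generate_model(cfg)$model
    iso <- identify_isozymes(m)
    expect_equal(iso[order(names(iso))],
                 oracle_isozymes(m)[order(names(oracle_isozymes(m)))])
    for (g in names(iso)) {
      expect_false(g %in% iso[[g]])
      for (g2 in iso[[g]]) expect_true(g %in% iso[[g2]])
    }
  }
})

test_that("pre-cap neighbor relation is symmetric; currency never connects", {
  for (s in 1:10) {
    cfg <- synthetic_config(n_reactions = 25L, n_genes_metabolic = 15L,
                            seed = 100 + s)
    gm <- generate_model(cfg)
    big <- extract_neighbors(gm$model, gm$truth$currency,
                             cap = 10000L, exclude = character(0))
    for (g in names(big$neighbors)) {
      for (g2 in big$neighbors[[g]]) {
        expect_true(g %in% big$neighbors[[g2]])
      }
      expect_false(any(big$connecting[[g]] %in% gm$truth$currency))
    }
  }
})

test_that("relatedness map exports TSV and GMT", {
  m <- chain_model()
  rel <- build_relatedness(m, currency_fraction = 0.9)  # nothing is currency
  tsv <- tempfile(fileext = ".tsv")
  gmt <- tempfile(fileext = ".gmt")
  write_relatedness_tsv(rel, tsv)
  tab <- read.delim(tsv)
  expect_true(all(c("gene", "related_gene", "relation_type",
                    "connecting_metabolite", "metabolite_degree") %in% names(tab)))
  expect_true(all(tab$relation_type %in% c("neighbor", "isozyme")))
  write_relatedness_gmt(rel, gmt)
  lines <- readLines(gmt)
  expect_true(any(grepl("^g2\\|neighbor\tmetdep\t", lines)))
})
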