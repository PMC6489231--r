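# Fixtures built in code and independent oracles used across test files.

# --- tiny hand-built models -------------------------------------------------

# Linear chain A ->(g1) B ->(g2) C ->(g3) D.
chain_model <- function() {
  mets <- data.frame(id = c("A", "B", "C", "D"), compartment = "c")
  rx <- list(
    metdep:::new_reaction("R1", data.frame(metabolite = "A", coef = 1),
                          data.frame(metabolite = "B", coef = 1), FALSE,
                          parse_gpr("g1")),
    metdep:::new_reaction("R2", data.frame(metabolite = "B", coef = 1),
                          data.frame(metabolite = "C", coef = 1), FALSE,
                          parse_gpr("g2")),
    metdep:::new_reaction("R3", data.frame(metabolite = "C", coef = 1),
                          data.frame(metabolite = "D", coef = 1), FALSE,
                          parse_gpr("g3"))
  )
  metabolic_model(mets, rx)
}

# Ten reactions with mixed AND/OR rules; enumerations asserted by hand in
# the model_io tests.
ten_reaction_rules <- c(
  R01 = "g1",
  R02 = "g1 or g2",
  R03 = "g2 and g3",
  R04 = "(g1 and g2) or g3",
  R05 = "g4 or g5 or g6",
  R06 = "g4 and (g5 or g7)",
  R07 = "",
  R08 = "g8",
  R09 = "(g1 or g9) and g10",
  R10 = "g9"
)

ten_reaction_model <- function() {
  mets <- data.frame(id = sprintf("m%02d", 1:11), compartment = "c")
  rx <- lapply(1:10, function(i) {
    metdep:::new_reaction(
      sprintf("R%02d", i),
      data.frame(metabolite = sprintf("m%02d", i), coef = 1),
      data.frame(metabolite = sprintf("m%02d", i + 1), coef = 1),
      i %% 2 == 0, parse_gpr(ten_reaction_rules[[i]]))
  })
  metabolic_model(mets, rx)
}

# --- SBML documents ---------------------------------------------------------

sbml_notes_doc <- function(gene_association = "g1", extra_species = "") {
  sprintf('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
 <model id="toy">
  <listOfSpecies>
   <species id="A_c" compartment="c"/>
   <species id="B_c" compartment="c"/>%s
  </listOfSpecies>
  <listOfReactions>
   <reaction id="R1" reversible="false">
    <notes><body xmlns="http://www.w3.org/1999/xhtml">
      <p>GENE_ASSOCIATION: %s</p>
    </body></notes>
    <listOfReactants><speciesReference species="A_c" stoichiometry="1"/></listOfReactants>
    <listOfProducts><speciesReference species="B_c" stoichiometry="1"/></listOfProducts>
   </reaction>
  </listOfReactions>
 </model>
</sbml>', extra_species, gene_association)
}

sbml_fbc_doc <- function() {
  '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
 <model id="toy" fbc:strict="false">
  <listOfSpecies>
   <species id="A_c" compartment="c"/>
   <species id="B_c" compartment="c"/>
  </listOfSpecies>
  <fbc:listOfGeneProducts>
   <fbc:geneProduct fbc:id="G_g1" fbc:label="g1"/>
   <fbc:geneProduct fbc:id="G_g2" fbc:label="g2"/>
   <fbc:geneProduct fbc:id="G_g3" fbc:label="g3"/>
  </fbc:listOfGeneProducts>
  <listOfReactions>
   <reaction id="R1" reversible="true">
    <listOfReactants><speciesReference species="A_c" stoichiometry="1"/></listOfReactants>
    <listOfProducts><speciesReference species="B_c" stoichiometry="2"/></listOfProducts>
    <fbc:geneProductAssociation>
     <fbc:or>
      <fbc:and>
       <fbc:geneProductRef fbc:geneProduct="G_g1"/>
       <fbc:geneProductRef fbc:geneProduct="G_g2"/>
      </fbc:and>
      <fbc:geneProductRef fbc:geneProduct="G_g3"/>
     </fbc:or>
    </fbc:geneProductAssociation>
   </reaction>
  </listOfReactions>
 </model>
</sbml>'
}

write_tmp <- function(text, ext = ".xml") {
  path <- tempfile(fileext = ext)
  writeLines(text, path)
  path
}

# --- independent oracles ----------------------------------------------------

# Exhaustive double-loop neighbor extraction, structured differently from
# the package implementation.
oracle_neighbors <- function(model, currency, cap = 50L, exclude = character(0)) {
  genes <- setdiff(model$genes, exclude)
  rx <- model$reactions
  mets_of <- lapply(rx, function(r) unique(c(r$substrates$metabolite,
                                             r$products$metabolite)))
  deg <- table(unlist(mets_of, use.names = FALSE))
  gene_rx <- lapply(stats::setNames(nm = genes), function(g) {
    which(vapply(rx, function(r) g %in% gpr_genes(r$gpr), logical(1)))
  })
  res <- list()
  for (g in genes) {
    best <- numeric(0)
    for (g2 in setdiff(genes, g)) {
      b <- Inf
      for (i in gene_rx[[g]]) {
        for (j in gene_rx[[g2]]) {
          for (m in intersect(mets_of[[i]], mets_of[[j]])) {
            if (!(m %in% currency)) b <- min(b, deg[[m]])
          }
        }
      }
      if (is.finite(b)) best[g2] <- b
    }
    ord <- order(best, names(best), method = "radix")
    res[[g]] <- utils::head(names(best)[ord], cap)
  }
  res
}

# Independent isozyme oracle: recursive lowest-common-ancestor check on the
# parsed rule tree (two genes are isozymes iff their LCA is an OR node).
oracle_isozymes <- function(model) {
  lca_or_pairs <- function(node) {
    if (is.null(node) || inherits(node, "gpr_leaf")) return(NULL)
    kids <- unclass(node)
    res <- do.call(rbind, lapply(kids, lca_or_pairs))
    if (inherits(node, "gpr_or")) {
      leafsets <- lapply(kids, gpr_genes)
      for (i in seq_along(leafsets)) for (j in seq_along(leafsets)) {
        if (i < j) {
          res <- rbind(res, expand.grid(a = leafsets[[i]], b = leafsets[[j]],
                                        stringsAsFactors = FALSE))
        }
      }
    }
    res
  }
  out <- lapply(stats::setNames(nm = model$genes), function(g) character(0))
  for (r in model$reactions) {
    prs <- lca_or_pairs(r$gpr)
    if (!is.null(prs)) for (k in seq_len(nrow(prs))) {
      a <- prs$a[k]; b <- prs$b[k]
      if (a != b) {
        out[[a]] <- union(out[[a]], b)
        out[[b]] <- union(out[[b]], a)
      }
    }
  }
  lapply(out, sort)
}

# --- hand-built screen datasets ---------------------------------------------

# Small deterministic dataset with explicit matrices, for tests that need
# full control over every value.
manual_dataset <- function(n_lines = 24, genes = c("gA", "gB"),
                           oncogenes = c("onc1", "onc2"), seed = 99,
                           medium = NULL, culture = NULL, lineage = NULL) {
  set.seed(seed)
  lines <- sprintf("c%02d", seq_len(n_lines))
  mk <- function(rows) matrix(rnorm(length(rows) * n_lines), length(rows),
                              n_lines, dimnames = list(rows, lines))
  ann <- data.frame(
    cell_line = lines,
    medium = medium %||% rep(c("DMEM", "RPMI"), length.out = n_lines),
    culture_type = culture %||% rep(c("adherent", "suspension"),
                                    length.out = n_lines),
    lineage = lineage %||% rep("lin1", n_lines),
    stringsAsFactors = FALSE)
  suppressMessages(screen_dataset(mk(genes), mk(genes),
                                  mk(genes), mk(oncogenes), ann,
                                  metabolic_genes = genes))
}

# A relatedness map built by hand.
manual_relatedness <- function(neighbors = list(), isozymes = list()) {
  structure(list(neighbors = neighbors, isozymes = isozymes,
                 currency = character(0),
                 connecting = lapply(neighbors, function(v)
                   stats::setNames(rep("m", length(v)), v)),
                 metabolite_degree = integer(0)),
            class = "relatedness_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
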