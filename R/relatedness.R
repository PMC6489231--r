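# Functional relatedness from the metabolic network: currency metabolites,
# capped neighboring-enzyme lists, isozyme sets.

#' Identify currency metabolites
#'
#' A metabolite is a currency metabolite when it participates (as substrate
#' or product) in strictly more than `fraction` of the reactions in the
#' network — the ubiquitous energy/redox carriers whose shared use carries
#' no functional signal. The threshold is a strict inequality: a metabolite
#' in exactly `fraction` of reactions is not currency.
#'
#' @param model A [metabolic_model()].
#' @param fraction Fraction of reactions, in (0,1). Default 0.01.
#' @param drop_exchange If `TRUE`, reactions with an empty substrate or
#'   product side (exchange/boundary reactions) are excluded from both the
#'   participation counts and the reaction total.
#' @return Character vector of currency metabolite ids.
#' @export
identify_currency_metabolites <- function(model, fraction = 0.01,
                                          drop_exchange = FALSE) {
  stopifnot(fraction > 0, fraction < 1)
  counts <- metabolite_reaction_counts(model, drop_exchange = drop_exchange)
  n_rx <- attr(counts, "n_reactions")
  if (n_rx == 0L) stop("model has no reactions")
  names(counts)[counts > fraction * n_rx]
}

# Per-metabolite count of distinct reactions it participates in.
metabolite_reaction_counts <- function(model, drop_exchange = FALSE) {
  reactions <- model$reactions
  if (drop_exchange) {
    keep <- vapply(reactions, function(r) {
      nrow(r$substrates) > 0L && nrow(r$products) > 0L
    }, logical(1))
    reactions <- reactions[keep]
  }
  part <- lapply(reactions, function(r) {
    unique(c(r$substrates$metabolite, r$products$metabolite))
  })
  tab <- table(unlist(part, use.names = FALSE))
  counts <- stats::setNames(rep(0L, nrow(model$metabolites)), model$metabolites$id)
  counts[names(tab)] <- as.integer(tab)
  attr(counts, "n_reactions") <- length(reactions)
  counts
}

#' Map genes to the reactions they catalyze
#'
#' A gene is a member of every reaction whose GPR tree contains it as a
#' leaf, regardless of AND/OR context.
#'
#' @param model A [metabolic_model()].
#' @return Named list: gene id -> character vector of reaction ids.
#' @export
gene_reaction_membership <- function(model) {
  out <- lapply(stats::setNames(nm = model$genes), function(g) character(0))
  for (r in model$reactions) {
    for (g in gpr_genes(r$gpr)) out[[g]] <- c(out[[g]], r$id)
  }
  out
}

#' Extract capped neighboring-enzyme lists
#'
#' Two genes are neighbors when some reaction of one and some reaction of
#' the other share a metabolite (substrate or product on either side;
#' direction and reversibility ignored) that is not a currency metabolite.
#' Candidates are ranked by the network-wide reaction-participation count of
#' their best (lowest-count) connecting metabolite, ascending, and only the
#' top `cap` are kept; ties are broken by lexicographic gene id for
#' determinism. Genes in `exclude` are removed entirely (they appear in no
#' list and get no list) — by default the signaling hubs EGFR and PIK-family
#' genes whose metabolic annotations would link unrelated pathways.
#'
#' @param model A [metabolic_model()].
#' @param currency Character vector of currency metabolite ids, typically
#'   from [identify_currency_metabolites()].
#' @param cap Maximum neighbors per gene (default 50).
#' @param exclude Genes excluded from the analysis. Default: ids starting
#'   with `EGFR` or `PIK`.
#' @return Named list with elements `neighbors` (gene -> ordered character
#'   vector), `connecting` (gene -> named vector mapping each neighbor to
#'   its best connecting metabolite) and `metabolite_degree` (named integer
#'   vector of reaction-participation counts).
#' @export
extract_neighbors <- function(model, currency = character(0), cap = 50L,
                              exclude = default_excluded_genes(model$genes)) {
  stopifnot(cap >= 1L)
  counts <- metabolite_reaction_counts(model)
  membership <- gene_reaction_membership(model)
  genes <- setdiff(model$genes, exclude)
  # reaction -> non-currency participants
  rx_mets <- lapply(model$reactions, function(r) {
    setdiff(unique(c(r$substrates$metabolite, r$products$metabolite)), currency)
  })
  # metabolite -> genes touching it (through any of their reactions)
  met_genes <- new.env(parent = emptyenv())
  for (g in genes) {
    for (rid in membership[[g]]) {
      for (m in rx_mets[[rid]]) {
        met_genes[[m]] <- c(met_genes[[m]], g)
      }
    }
  }
  neighbors <- list()
  connecting <- list()
  for (g in genes) {
    mets <- unique(unlist(rx_mets[membership[[g]]], use.names = FALSE))
    if (is.null(mets)) mets <- character(0)
    # best (lowest-degree) connecting metabolite per candidate neighbor
    best_met <- character(0)
    best_deg <- integer(0)
    for (m in sort(mets)) {
      for (g2 in unique(met_genes[[m]])) {
        if (g2 == g) next
        i <- match(g2, names(best_deg))
        if (is.na(i)) {
          best_deg[g2] <- counts[[m]]
          best_met[g2] <- m
        } else if (counts[[m]] < best_deg[[i]]) {
          best_deg[[i]] <- counts[[m]]
          best_met[[i]] <- m
        }
      }
    }
    if (length(best_deg)) {
      ord <- order(best_deg, names(best_deg), method = "radix")
      keep <- utils::head(ord, cap)
      neighbors[[g]] <- names(best_deg)[keep]
      connecting[[g]] <- stats::setNames(best_met[keep], names(best_deg)[keep])
    } else {
      neighbors[[g]] <- character(0)
      connecting[[g]] <- stats::setNames(character(0), character(0))
    }
  }
  list(neighbors = neighbors, connecting = connecting,
       metabolite_degree = counts)
}

#' Default excluded genes: EGFR and PIK-family identifiers
#' @param genes Character vector of model gene ids.
#' @return The subset matching `^EGFR` or `^PIK` (config-editable by passing
#'   an explicit `exclude` to [extract_neighbors()]).
#' @export
default_excluded_genes <- function(genes) {
  genes[grepl("^(EGFR|PIK)", genes)]
}

#' Identify isozymes from GPR rules
#'
#' Two genes are isozymes when they occur in some reaction's GPR as
#' OR-alternatives: their lowest common ancestor in the rule tree is an OR
#' node. Genes joined only by AND are complex partners, not isozymes. The
#' relation is symmetric and irreflexive.
#'
#' @param model A [metabolic_model()].
#' @return Named list: gene -> character vector of isozymes (sorted).
#' @export
identify_isozymes <- function(model) {
  out <- lapply(stats::setNames(nm = model$genes), function(g) character(0))
  for (r in model$reactions) {
    prs <- gpr_or_pairs(r$gpr)
    if (nrow(prs)) {
      for (k in seq_len(nrow(prs))) {
        a <- prs[k, 1]; b <- prs[k, 2]
        if (a != b) {
          out[[a]] <- c(out[[a]], b)
          out[[b]] <- c(out[[b]], a)
        }
      }
    }
  }
  lapply(out, function(v) sort(unique(v)))
}

#' Build the full relatedness map for a model
#'
#' Convenience wrapper running currency identification, neighbor extraction
#' and isozyme identification with the standard defaults.
#'
#' @param model A [metabolic_model()].
#' @param currency_fraction Currency threshold (default 0.01, strict `>`).
#' @param cap Neighbor cap (default 50).
#' @param exclude Excluded genes; see [extract_neighbors()].
#' @param drop_exchange Passed to [identify_currency_metabolites()].
#' @return Object of class `relatedness_map`: list with `neighbors`,
#'   `isozymes`, `currency`, `connecting`, `metabolite_degree`.
#' @export
build_relatedness <- function(model, currency_fraction = 0.01, cap = 50L,
                              exclude = default_excluded_genes(model$genes),
                              drop_exchange = FALSE) {
  currency <- identify_currency_metabolites(model, currency_fraction,
                                            drop_exchange = drop_exchange)
  nb <- extract_neighbors(model, currency, cap = cap, exclude = exclude)
  iso <- identify_isozymes(model)
  iso[exclude] <- NULL
  iso <- lapply(iso, function(v) setdiff(v, exclude))
  structure(list(neighbors = nb$neighbors, isozymes = iso,
                 currency = currency, connecting = nb$connecting,
                 metabolite_degree = nb$metabolite_degree),
            class = "relatedness_map")
}

#' @export
print.relatedness_map <- function(x, ...) {
  cat(sprintf("<relatedness_map> %d genes, %d currency metabolites; median neighbors %s\n",
              length(x$neighbors), length(x$currency),
              stats::median(lengths(x$neighbors))))
  invisible(x)
}

#' Write a relatedness map as a long TSV
#'
#' One row per (gene, related gene) with the relation type, the connecting
#' metabolite (neighbors only) and that metabolite's reaction count.
#'
#' @param relatedness A `relatedness_map` from [build_relatedness()].
#' @param path Output TSV path.
#' @export
write_relatedness_tsv <- function(relatedness, path) {
  rows <- list()
  for (g in names(relatedness$neighbors)) {
    nb <- relatedness$neighbors[[g]]
    if (length(nb)) {
      met <- relatedness$connecting[[g]][nb]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, related_gene = nb, relation_type = "neighbor",
        connecting_metabolite = unname(met),
        metabolite_degree = unname(relatedness$metabolite_degree[met]),
        stringsAsFactors = FALSE)
    }
  }
  for (g in names(relatedness$isozymes)) {
    iso <- relatedness$isozymes[[g]]
    if (length(iso)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, related_gene = iso, relation_type = "isozyme",
        connecting_metabolite = NA_character_, metabolite_degree = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(gene = character(0), related_gene = character(0),
               relation_type = character(0), connecting_metabolite = character(0),
               metabolite_degree = integer(0))
  }
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write neighbor/isozyme sets in GMT format
#'
#' One line per gene and relation type: `GENE|neighbor<TAB>metdep<TAB>g1...`.
#'
#' @param relatedness A `relatedness_map`.
#' @param path Output path.
#' @export
write_relatedness_gmt <- function(relatedness, path) {
  lines <- character(0)
  for (type in c("neighbors", "isozymes")) {
    sets <- relatedness[[type]]
    tag <- sub("s$", "", type)
    for (g in names(sets)) {
      if (length(sets[[g]])) {
        lines <- c(lines, paste(c(paste0(g, "|", tag), "metdep", sets[[g]]),
                                collapse = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
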