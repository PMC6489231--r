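# Synthetic toy metabolic models and screen datasets with known ground
# truth, emulating the structure of pan-cancer essentiality screens:
# continuous dependency scores (lower = more essential), log-scale
# expression, copy-number ratios around 1, Bernoulli oncogene mutations,
# and categorical media / culture-type / lineage labels with a plantable
# media-culture confounding structure.

#' Synthetic screen configuration
#'
#' Defaults describe the desk-scale world the test-suite exercises: 200
#' cell lines, ~300 screened genes (60 metabolic + 240 other), four media
#' with RPMI and DMEM dominant (as in the real screens), six lineages with
#' skewed sizes so some fall below the 10-line modeling rule, 125
#' oncogenes, and unit noise so planted effect sizes are in noise-SD units.
#'
#' @param n_reactions Reactions in the toy network (default 60).
#' @param n_genes_metabolic Metabolic gene pool size (default 60).
#' @param n_genes_other Non-metabolic screened genes (default 240).
#' @param n_cell_lines Cell lines (default 200).
#' @param media Named probabilities of media labels (default RPMI .55,
#'   DMEM .25, McCoy .10, HamsF12 .10).
#' @param n_lineages Lineage count (default 6); sizes are drawn from a
#'   geometric profile so small lineages occur.
#' @param n_oncogenes Oncogene mutation panel size (default 125).
#' @param mutation_rate Bernoulli rate per oncogene x line (default 0.05).
#' @param currency_fraction_target Fraction of reactions each hub
#'   metabolite participates in (default 0.05, above the 0.01 currency
#'   threshold by construction).
#' @param n_hub_metabolites Hub (currency) metabolites (default 2).
#' @param planted_effects List of [planted_effect()]s.
#' @param noise_sd Dependency noise SD (default 1); effect sizes are
#'   expressed in these units.
#' @param media_culture_confounding Strength in \[0,1\] of the planted
#'   adherent->DMEM / suspension->RPMI bias (default 0.6), giving the
#'   partial-correlation controls something real to disentangle.
#' @param adherent_fraction Fraction of adherent lines (default 0.7).
#' @param lineage_media_bias Optional list(lineage = index, medium = label,
#'   strength = p): lines of that lineage get that medium with probability
#'   `strength`, overriding the culture-type assignment — the
#'   lineage-confounded scenario.
#' @param seed Integer seed recorded in every output.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_reactions = 60L, n_genes_metabolic = 60L,
                             n_genes_other = 240L, n_cell_lines = 200L,
                             media = c(RPMI = 0.55, DMEM = 0.25,
                                       McCoy = 0.10, HamsF12 = 0.10),
                             n_lineages = 6L, n_oncogenes = 125L,
                             mutation_rate = 0.05,
                             currency_fraction_target = 0.05,
                             n_hub_metabolites = 2L,
                             planted_effects = list(), noise_sd = 1,
                             media_culture_confounding = 0.6,
                             adherent_fraction = 0.7,
                             lineage_media_bias = NULL, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_reactions >= 1, n_genes_metabolic >= 1, n_cell_lines >= 1,
            n_lineages >= 1, n_oncogenes >= 1, noise_sd > 0,
            abs(sum(media) - 1) < 1e-8,
            currency_fraction_target > 0.01, currency_fraction_target < 1,
            media_culture_confounding >= 0, media_culture_confounding <= 1)
  structure(cfg, class = "synthetic_config")
}

#' Declare a planted ground-truth effect
#'
#' The effect kinds mirror the phenomena the pipeline is built to detect:
#' `media_shift` (a gene more essential under one medium, the ASNS-like
#' scenario), `self_expression` / `isozyme_expression` /
#' `neighbor_expression` (dependency coupled to an expression level),
#' `mutation_conditional` (coupling active only in mutated lines — the
#' synthetic-lethality scenario), and `lineage_shift` (essentiality tied to
#' a lineage). Effect sizes are in noise-SD units; the default direction
#' `-1` means "more essential" (lower scores).
#'
#' @param kind One of the six kinds above.
#' @param gene Target gene id.
#' @param effect_size Positive effect size in noise-SD units. For
#'   `mutation_conditional` this is the within-mutant coupling slope.
#' @param direction `-1` (more essential; default) or `+1`.
#' @param medium,partner,oncogene,lineage Conditioning feature, as the kind
#'   requires.
#' @param shift `mutation_conditional` only: mean dependency shift of
#'   mutated lines, in noise-SD units (default `effect_size / 2`). The
#'   mutant contribution is `direction * noise_sd * mut * (effect_size * z
#'   + shift)` with `z` the standardized partner expression.
#' @return List of class `planted_effect`.
#' @export
planted_effect <- function(kind = c("media_shift", "self_expression",
                                    "neighbor_expression",
                                    "isozyme_expression",
                                    "mutation_conditional", "lineage_shift"),
                           gene, effect_size, direction = -1,
                           medium = NULL, partner = NULL, oncogene = NULL,
                           lineage = NULL, shift = effect_size / 2) {
  kind <- match.arg(kind)
  stopifnot(effect_size != 0, direction %in% c(-1, 1))
  structure(list(kind = kind, gene = gene, effect_size = effect_size,
                 direction = direction, medium = medium, partner = partner,
                 oncogene = oncogene, lineage = lineage, shift = shift),
            class = "planted_effect")
}

#' Generate a toy metabolic model with known relatedness
#'
#' Random sparse reaction network over compartment-qualified metabolites;
#' `n_hub_metabolites` hubs are attached to `currency_fraction_target` of
#' the reactions, placing them above the 1% currency threshold by
#' construction. GPRs mix single-gene, OR (isozyme) and AND (complex)
#' rules. The returned ground truth is computed by independent construction
#' bookkeeping (an exhaustive double loop over the recorded participant
#' lists), not by the package's extraction path, so it can serve as an
#' oracle.
#'
#' @param config A [synthetic_config()].
#' @param truth_cap Neighbor cap used for the ground-truth map (default 50).
#' @return List with `model` (a [metabolic_model()]) and `truth` (list
#'   `neighbors`, `isozymes`, `currency`).
#' @export
generate_model <- function(config, truth_cap = 50L) {
  stopifnot(inherits(config, "synthetic_config"))
  n_rx <- config$n_reactions
  n_plain <- max(8L, ceiling(n_rx * 0.7))
  if (config$n_hub_metabolites >= n_plain) {
    stop("infeasible config: more hub metabolites than ordinary metabolites")
  }
  rng <- local_rng(derive_seed(config$seed, 101L))
  on.exit(rng$restore())
  comps <- c("c", "m")
  plain <- sprintf("met%03d_%s", seq_len(n_plain),
                   sample(comps, n_plain, replace = TRUE))
  hubs <- if (config$n_hub_metabolites > 0) {
    sprintf("hub%02d_c", seq_len(config$n_hub_metabolites))
  } else character(0)
  metabolites <- data.frame(id = c(plain, hubs),
                            compartment = sub("^.*_", "", c(plain, hubs)),
                            stringsAsFactors = FALSE)
  pool <- sprintf("MG%04d", seq_len(config$n_genes_metabolic))

  # hub attachment: each hub joins ceil(target * n_rx) distinct reactions
  hub_rx <- lapply(hubs, function(h) {
    sample.int(n_rx, ceiling(config$currency_fraction_target * n_rx))
  })

  reactions <- vector("list", n_rx)
  participants <- vector("list", n_rx)  # construction record: non-hub mets
  rule_genes <- vector("list", n_rx)    # construction record: gene leaves
  rule_types <- character(n_rx)         # construction record: rule kind
  for (i in seq_len(n_rx)) {
    k_s <- sample(1:2, 1); k_p <- sample(1:2, 1)
    mets <- sample(plain, k_s + k_p)
    subs <- mets[seq_len(k_s)]; prods <- mets[k_s + seq_len(k_p)]
    for (h in seq_along(hubs)) {
      if (i %in% hub_rx[[h]]) {
        if (stats::runif(1) < 0.5) subs <- c(subs, hubs[h]) else prods <- c(prods, hubs[h])
      }
    }
    type <- sample(c("single", "or", "and"), 1, prob = c(0.6, 0.2, 0.2))
    genes <- if (type == "single") sample(pool, 1) else sample(pool, 2)
    rule <- switch(type,
      single = genes,
      or = paste(genes, collapse = " or "),
      and = paste(genes, collapse = " and "))
    reactions[[i]] <- new_reaction(
      sprintf("R%03d", i),
      data.frame(metabolite = subs, coef = rep(1, length(subs))),
      data.frame(metabolite = prods, coef = rep(1, length(prods))),
      reversible = stats::runif(1) < 0.3,
      gpr = parse_gpr(rule))
    participants[[i]] <- c(subs, prods)
    rule_genes[[i]] <- genes
    rule_types[i] <- type
  }
  model <- metabolic_model(metabolites, reactions)

  truth <- truth_from_construction(participants, rule_genes, rule_types,
                                   hubs, model$genes, truth_cap)
  list(model = model, truth = truth)
}

# Exhaustive double-loop ground truth from the construction records.
truth_from_construction <- function(participants, rule_genes, rule_types,
                                    hubs, genes, cap) {
  n_rx <- length(participants)
  met_count <- table(unlist(lapply(participants, unique), use.names = FALSE))
  gene_rx <- lapply(stats::setNames(nm = genes), function(g) {
    which(vapply(rule_genes, function(v) g %in% v, logical(1)))
  })
  neighbors <- list()
  for (g in genes) {
    cand_deg <- integer(0)
    for (g2 in genes) {
      if (g2 == g) next
      best <- Inf
      for (i in gene_rx[[g]]) {
        for (j in gene_rx[[g2]]) {
          shared <- setdiff(intersect(participants[[i]], participants[[j]]), hubs)
          for (m in shared) best <- min(best, met_count[[m]])
        }
      }
      if (is.finite(best)) cand_deg[g2] <- best
    }
    ord <- order(cand_deg, names(cand_deg), method = "radix")
    neighbors[[g]] <- utils::head(names(cand_deg)[ord], cap)
  }
  isozymes <- lapply(stats::setNames(nm = genes), function(g) character(0))
  for (i in which(rule_types == "or")) {
    pr <- rule_genes[[i]]
    if (pr[1] != pr[2]) {
      isozymes[[pr[1]]] <- sort(unique(c(isozymes[[pr[1]]], pr[2])))
      isozymes[[pr[2]]] <- sort(unique(c(isozymes[[pr[2]]], pr[1])))
    }
  }
  list(neighbors = neighbors, isozymes = isozymes, currency = hubs)
}

#' Generate a synthetic screen dataset with planted effects
#'
#' Expression is per-gene Gaussian on a log scale, copy number Gaussian
#' around 1 with occasional amplifications, mutations Bernoulli, media
#' correlated with culture type (and optionally with one lineage), and
#' dependency scores are Gaussian noise plus the planted contributions.
#' A `neighbor_expression`/`isozyme_expression` effect whose partner is not
#' a ground-truth neighbor/isozyme of the target is an error, keeping the
#' planted structure honest.
#'
#' @param config A [synthetic_config()].
#' @param model,truth From [generate_model()].
#' @return List with `dataset` (a [screen_dataset()]) and `registry`
#'   (data.frame of planted effects with their conditioning features).
#' @export
generate_screen <- function(config, model, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  rng <- local_rng(derive_seed(config$seed, 202L))
  on.exit(rng$restore())
  n <- config$n_cell_lines
  lines <- sprintf("CL%04d", seq_len(n))
  metabolic <- model$genes
  others <- if (config$n_genes_other > 0) {
    sprintf("OG%04d", seq_len(config$n_genes_other))
  } else character(0)
  all_genes <- c(metabolic, others)

  culture <- ifelse(stats::runif(n) < config$adherent_fraction,
                    "adherent", "suspension")
  media_levels <- names(config$media)
  s <- config$media_culture_confounding
  medium <- vapply(culture, function(ct) {
    target <- if (ct == "adherent") "DMEM" else "RPMI"
    probs <- (1 - s) * config$media
    if (target %in% media_levels) probs[target] <- probs[target] + s
    sample(media_levels, 1, prob = probs)
  }, character(1), USE.NAMES = FALSE)

  lin_probs <- 0.55^(seq_len(config$n_lineages) - 1)
  lineage <- sample(sprintf("lineage%02d", seq_len(config$n_lineages)), n,
                    replace = TRUE, prob = lin_probs / sum(lin_probs))
  if (!is.null(config$lineage_media_bias)) {
    b <- config$lineage_media_bias
    target_lin <- sprintf("lineage%02d", b$lineage)
    in_lin <- lineage == target_lin
    flip <- in_lin & stats::runif(n) < b$strength
    medium[flip] <- b$medium
  }
  annotations <- data.frame(cell_line = lines, medium = medium,
                            culture_type = culture, lineage = lineage,
                            stringsAsFactors = FALSE)

  gmeans <- stats::rnorm(length(all_genes), 6, 2)
  expression <- matrix(stats::rnorm(length(all_genes) * n, 0, 1),
                       nrow = length(all_genes)) + gmeans
  dimnames(expression) <- list(all_genes, lines)
  cnv <- matrix(1 + stats::rnorm(length(all_genes) * n, 0, 0.15),
                nrow = length(all_genes), dimnames = list(all_genes, lines))
  amp <- matrix(stats::runif(length(cnv)) < 0.02, nrow = nrow(cnv))
  cnv[amp] <- cnv[amp] + 1
  oncs <- sprintf("ONC%03d", seq_len(config$n_oncogenes))
  mutations <- matrix(as.numeric(stats::runif(config$n_oncogenes * n) <
                                   config$mutation_rate),
                      nrow = config$n_oncogenes, dimnames = list(oncs, lines))
  dependency <- matrix(stats::rnorm(length(all_genes) * n, 0, config$noise_sd),
                       nrow = length(all_genes), dimnames = list(all_genes, lines))

  registry <- list()
  for (eff in config$planted_effects) {
    stopifnot(inherits(eff, "planted_effect"))
    g <- eff$gene
    if (!g %in% all_genes) stop("planted effect targets unknown gene ", g)
    delta <- eff$direction * eff$effect_size * config$noise_sd
    cond <- ""
    switch(eff$kind,
      media_shift = {
        stopifnot(!is.null(eff$medium))
        sel <- medium == eff$medium
        dependency[g, sel] <- dependency[g, sel] + delta
        cond <- eff$medium
      },
      lineage_shift = {
        stopifnot(!is.null(eff$lineage))
        target_lin <- if (is.numeric(eff$lineage)) {
          sprintf("lineage%02d", eff$lineage)
        } else eff$lineage
        sel <- lineage == target_lin
        dependency[g, sel] <- dependency[g, sel] + delta
        cond <- target_lin
      },
      self_expression = {
        z <- as.numeric(scale(expression[g, ]))
        dependency[g, ] <- dependency[g, ] + delta * z
        cond <- g
      },
      neighbor_expression = {
        p <- eff$partner
        if (is.null(p) || !p %in% truth$neighbors[[g]]) {
          stop("planted neighbor_expression partner ", p %||% "<NULL>",
               " is not a ground-truth neighbor of ", g)
        }
        z <- as.numeric(scale(expression[p, ]))
        dependency[g, ] <- dependency[g, ] + delta * z
        cond <- p
      },
      isozyme_expression = {
        p <- eff$partner
        if (is.null(p) || !p %in% truth$isozymes[[g]]) {
          stop("planted isozyme_expression partner ", p %||% "<NULL>",
               " is not a ground-truth isozyme of ", g)
        }
        z <- as.numeric(scale(expression[p, ]))
        dependency[g, ] <- dependency[g, ] + delta * z
        cond <- p
      },
      mutation_conditional = {
        stopifnot(!is.null(eff$oncogene))
        p <- eff$partner %||% g
        z <- as.numeric(scale(expression[p, ]))
        mut <- mutations[eff$oncogene, ]
        contrib <- eff$direction * config$noise_sd *
          (eff$effect_size * z + eff$shift)
        dependency[g, ] <- dependency[g, ] + contrib * mut
        cond <- paste0(eff$oncogene, "&", p)
      })
    registry[[length(registry) + 1L]] <- data.frame(
      kind = eff$kind, gene = g, conditioning = cond,
      effect_size = eff$effect_size, direction = eff$direction,
      seed = config$seed, stringsAsFactors = FALSE)
  }
  registry <- if (length(registry)) do.call(rbind, registry) else {
    data.frame(kind = character(0), gene = character(0),
               conditioning = character(0), effect_size = numeric(0),
               direction = numeric(0), seed = integer(0))
  }
  dataset <- suppressMessages(screen_dataset(
    dependency, expression, cnv, mutations, annotations,
    metabolic_genes = metabolic))
  list(dataset = dataset, registry = registry)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic fixture to disk
#'
#' Writes the tabular model dialect plus the five screen files in exactly
#' the formats [read_tabular_model()] and [load_screen()] consume, the
#' metabolic gene list, and (when given) the ground-truth registry as JSON.
#' All paths inside the directory are relative, so the fixture is
#' self-contained.
#'
#' @param dataset A [screen_dataset()].
#' @param model A [metabolic_model()] or `NULL`.
#' @param dir Output directory (created if needed).
#' @param registry Optional registry data.frame from [generate_screen()].
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(dataset, model, dir, registry = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(dependency = "dependency.tsv", expression = "expression.tsv",
             cnv = "cnv.tsv", mutations = "mutations.tsv",
             annotations = "annotations.tsv")
  write_mat <- function(m, path) {
    dt <- data.table::data.table(gene = rownames(m))
    dt <- cbind(dt, data.table::as.data.table(m))
    data.table::fwrite(dt, path, sep = "\t")
  }
  for (nm in c("dependency", "expression", "cnv", "mutations")) {
    write_mat(dataset[[nm]], file.path(dir, paths[[nm]]))
  }
  data.table::fwrite(dataset$annotations, file.path(dir, paths[["annotations"]]),
                     sep = "\t")
  writeLines(dataset$metabolic_genes, file.path(dir, "metabolic_genes.txt"))
  out <- file.path(dir, c(paths, metabolic_genes = "metabolic_genes.txt"))
  if (!is.null(model)) {
    write_tabular_model(model, file.path(dir, "reactions.tsv"),
                        file.path(dir, "gpr.tsv"))
    out <- c(out, file.path(dir, c("reactions.tsv", "gpr.tsv")))
  }
  if (!is.null(registry)) {
    jsonlite::write_json(registry, file.path(dir, "registry.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    out <- c(out, file.path(dir, "registry.json"))
  }
  invisible(out)
}

#' Load a fixture directory written by [write_fixture()]
#'
#' @param dir Fixture directory.
#' @return A [screen_dataset()].
#' @export
load_fixture <- function(dir) {
  mg_path <- file.path(dir, "metabolic_genes.txt")
  load_screen(file.path(dir, "dependency.tsv"),
              file.path(dir, "expression.tsv"),
              file.path(dir, "cnv.tsv"),
              file.path(dir, "mutations.tsv"),
              file.path(dir, "annotations.tsv"),
              metabolic_genes = if (file.exists(mg_path)) readLines(mg_path)
                                else character(0))
}
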