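# Metabolic model container and readers (SBML and a tabular dialect).

#' Construct a metabolic model
#'
#' The in-memory representation used throughout the package: the model is a
#' graph of reactions over compartment-qualified metabolites, annotated with
#' parsed gene-protein-reaction (GPR) rules. Compartmentalized pools of the
#' same chemical (e.g. cytosolic vs mitochondrial) are distinct metabolites;
#' adjacency never crosses a membrane implicitly.
#'
#' @param metabolites data.frame with columns `id`, `compartment`.
#' @param reactions list of reactions; each a list with `id`, `substrates`
#'   (data.frame `metabolite`, `coef` with coef > 0), `products` (same),
#'   `reversible` (logical) and `gpr` (parsed tree from [parse_gpr()] or
#'   `NULL`).
#' @return Object of class `metabolic_model` with fields `metabolites`,
#'   `reactions` and `genes` (union of all GPR leaves).
#' @export
metabolic_model <- function(metabolites, reactions) {
  stopifnot(is.data.frame(metabolites), all(c("id", "compartment") %in% names(metabolites)))
  metabolites$id <- as.character(metabolites$id)
  metabolites$compartment <- as.character(metabolites$compartment)
  if (anyDuplicated(metabolites$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  }
  if (any(!nzchar(metabolites$compartment))) stop("empty compartment label")
  rids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids)) {
    stop("duplicate reaction ids: ", paste(unique(rids[duplicated(rids)]), collapse = ", "))
  }
  names(reactions) <- rids
  for (r in reactions) {
    for (side in c("substrates", "products")) {
      tab <- r[[side]]
      stopifnot(is.data.frame(tab), all(c("metabolite", "coef") %in% names(tab)))
      if (any(tab$coef <= 0)) {
        stop(sprintf("reaction %s: non-positive stoichiometric coefficient", r$id))
      }
      missing <- setdiff(tab$metabolite, metabolites$id)
      if (length(missing)) {
        stop(sprintf("reaction %s references unknown species: %s",
                     r$id, paste(missing, collapse = ", ")))
      }
    }
    if (length(intersect(r$substrates$metabolite, r$products$metabolite))) {
      stop(sprintf("reaction %s: metabolite on both sides", r$id))
    }
  }
  genes <- sort(unique(unlist(lapply(reactions, function(r) gpr_genes(r$gpr)),
                              use.names = FALSE)))
  structure(list(metabolites = metabolites, reactions = reactions,
                 genes = genes), class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %d metabolites, %d reactions, %d genes\n",
              nrow(x$metabolites), length(x$reactions), length(x$genes)))
  invisible(x)
}

# Long participation table: one row per (reaction, metabolite, role).
model_participation <- function(model) {
  rows <- lapply(model$reactions, function(r) {
    rbind(
      if (nrow(r$substrates)) data.frame(reaction = r$id, metabolite = r$substrates$metabolite,
                                         role = "substrate", coef = r$substrates$coef,
                                         stringsAsFactors = FALSE),
      if (nrow(r$products)) data.frame(reaction = r$id, metabolite = r$products$metabolite,
                                       role = "product", coef = r$products$coef,
                                       stringsAsFactors = FALSE)
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(reaction = character(0), metabolite = character(0),
                      role = character(0), coef = numeric(0))
  }
  rownames(out) <- NULL
  out
}

new_reaction <- function(id, substrates, products, reversible, gpr) {
  empty <- data.frame(metabolite = character(0), coef = numeric(0))
  fix <- function(tab) {
    if (is.null(tab) || nrow(tab) == 0L) return(empty)
    data.frame(metabolite = as.character(tab$metabolite), coef = as.numeric(tab$coef))
  }
  list(id = id, substrates = fix(substrates), products = fix(products),
       reversible = isTRUE(reversible), gpr = gpr)
}

#' Read a genome-scale metabolic model from SBML
#'
#' Supports SBML Level 2 and Level 3 documents. Gene associations are read
#' from either dialect: the legacy `GENE_ASSOCIATION:` line in reaction
#' `<notes>`, or the Level 3 `fbc:geneProductAssociation` element (gene
#' products are mapped to their `label` when available, else their id).
#' Species that take part in no reaction are retained as metabolites.
#'
#' @param path Path to an SBML file.
#' @return A [metabolic_model()].
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- xml2::read_xml(path)  # malformed XML errors name the offending line
  ns <- xml2::xml_ns(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  metabolites <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    stringsAsFactors = FALSE
  )
  metabolites$compartment[is.na(metabolites$compartment)] <- "default"

  # fbc gene products: id -> label
  gp_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  gp_label <- character(0)
  if (length(gp_nodes)) {
    gp_id <- xml2::xml_attr(gp_nodes, "id")
    lab <- xml2::xml_attr(gp_nodes, "label")
    lab[is.na(lab)] <- gp_id[is.na(lab)]
    gp_label <- stats::setNames(lab, gp_id)
  }

  rx_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  reactions <- lapply(rx_nodes, function(node) {
    rid <- xml2::xml_attr(node, "id")
    side <- function(listname) {
      refs <- xml2::xml_find_all(node, sprintf(
        "./*[local-name()='%s']/*[local-name()='speciesReference']", listname))
      if (!length(refs)) return(NULL)
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coef[is.na(coef)] <- 1
      data.frame(metabolite = xml2::xml_attr(refs, "species"), coef = coef,
                 stringsAsFactors = FALSE)
    }
    rev_attr <- xml2::xml_attr(node, "reversible")
    reversible <- is.na(rev_attr) || tolower(rev_attr) == "true"
    gpr <- sbml_reaction_gpr(node, gp_label)
    new_reaction(rid, side("listOfReactants"), side("listOfProducts"),
                 reversible, gpr)
  })

  # name unresolved species in terms of the reaction that references them
  known <- metabolites$id
  for (r in reactions) {
    bad <- setdiff(c(r$substrates$metabolite, r$products$metabolite), known)
    if (length(bad)) {
      stop(sprintf("SBML validation: reaction %s references undeclared species %s",
                   r$id, paste(bad, collapse = ", ")))
    }
  }
  metabolic_model(metabolites, reactions)
}

sbml_reaction_gpr <- function(node, gp_label) {
  assoc <- xml2::xml_find_first(node, "./*[local-name()='geneProductAssociation']")
  if (!inherits(assoc, "xml_missing")) {
    kids <- xml2::xml_children(assoc)
    if (length(kids) == 0L) return(NULL)
    return(fbc_to_gpr(kids[[1]], gp_label))
  }
  notes <- xml2::xml_find_first(node, "./*[local-name()='notes']")
  if (inherits(notes, "xml_missing")) return(NULL)
  txt <- xml2::xml_text(notes)
  m <- regmatches(txt, regexec("GENE[ _]ASSOCIATION:([^\n<]*)", txt))[[1]]
  if (length(m) < 2L) return(NULL)
  parse_gpr(trimws(m[2]))
}

fbc_to_gpr <- function(node, gp_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    gene <- if (ref %in% names(gp_label)) gp_label[[ref]] else ref
    return(structure(gene, class = "gpr_leaf"))
  }
  kids <- lapply(xml2::xml_children(node), fbc_to_gpr, gp_label = gp_label)
  cls <- switch(nm, "and" = "gpr_and", "or" = "gpr_or",
                stop("unknown fbc association element: ", nm))
  gpr_node(cls, kids)
}

#' Read a metabolic model from the tabular dialect
#'
#' The tabular fallback makes the pipeline testable without an SBML model.
#' `reactions_path` is a TSV with columns `reaction`, `metabolite`,
#' `compartment`, `coef` (signed: negative = substrate, positive = product)
#' and `reversible`; `gpr_path` is a TSV with columns `reaction`, `rule`.
#' Reactions absent from the GPR table get an empty rule.
#'
#' @param reactions_path,gpr_path Paths to the two TSV files.
#' @return A [metabolic_model()]; semantics identical to [read_sbml()].
#' @export
read_tabular_model <- function(reactions_path, gpr_path) {
  rx <- data.table::fread(reactions_path, sep = "\t", colClasses = list(
    character = c("reaction", "metabolite", "compartment")))
  need <- c("reaction", "metabolite", "compartment", "coef", "reversible")
  if (!all(need %in% names(rx))) {
    stop("reactions table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(rx$coef == 0)) {
    bad <- rx$reaction[rx$coef == 0][1]
    stop("zero stoichiometric coefficient in reaction ", bad)
  }
  gpr_tab <- data.table::fread(gpr_path, sep = "\t",
                               colClasses = list(character = 1:2))
  if (!all(c("reaction", "rule") %in% names(gpr_tab))) {
    stop("gpr table must have columns: reaction, rule")
  }
  unknown <- setdiff(gpr_tab$reaction, rx$reaction)
  if (length(unknown)) {
    stop("gpr table references unknown reaction ids: ",
         paste(unknown, collapse = ", "))
  }
  metabolites <- unique(data.frame(id = rx$metabolite, compartment = rx$compartment,
                                   stringsAsFactors = FALSE))
  if (anyDuplicated(metabolites$id)) {
    stop("metabolite listed with two different compartments")
  }
  rules <- stats::setNames(as.list(gpr_tab$rule), gpr_tab$reaction)
  reactions <- lapply(split(as.data.frame(rx), rx$reaction), function(part) {
    rid <- part$reaction[1]
    new_reaction(
      rid,
      data.frame(metabolite = part$metabolite[part$coef < 0], coef = -part$coef[part$coef < 0]),
      data.frame(metabolite = part$metabolite[part$coef > 0], coef = part$coef[part$coef > 0]),
      as.logical(part$reversible[1]),
      parse_gpr(if (rid %in% names(rules)) rules[[rid]] else "")
    )
  })
  # keep the file's reaction order
  reactions <- reactions[unique(rx$reaction)]
  metabolic_model(metabolites, reactions)
}

#' Write a metabolic model in the tabular dialect
#'
#' Inverse of [read_tabular_model()]: a written model round-trips to an
#' equal model on every field used downstream.
#'
#' @param model A [metabolic_model()].
#' @param reactions_path,gpr_path Output paths (UTF-8 TSV).
#' @export
write_tabular_model <- function(model, reactions_path, gpr_path) {
  comp <- stats::setNames(model$metabolites$compartment, model$metabolites$id)
  rows <- lapply(model$reactions, function(r) {
    data.frame(
      reaction = r$id,
      metabolite = c(r$substrates$metabolite, r$products$metabolite),
      compartment = comp[c(r$substrates$metabolite, r$products$metabolite)],
      coef = c(-r$substrates$coef, r$products$coef),
      reversible = r$reversible,
      stringsAsFactors = FALSE
    )
  })
  rx <- do.call(rbind, rows)
  data.table::fwrite(rx, reactions_path, sep = "\t")
  gpr_tab <- data.frame(
    reaction = names(model$reactions),
    rule = vapply(model$reactions, function(r) gpr_to_string(r$gpr), character(1)),
    stringsAsFactors = FALSE
  )
  gpr_tab <- gpr_tab[nzchar(gpr_tab$rule), , drop = FALSE]
  data.table::fwrite(gpr_tab, gpr_path, sep = "\t")
  invisible(c(reactions_path, gpr_path))
}
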