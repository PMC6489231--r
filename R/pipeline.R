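# Pipeline driver: configuration, orchestration of the analysis stages,
# output tables and run manifest, and a human-readable summary.

default_config <- function() {
  list(
    # inputs
    sbml_path = NULL, reactions_path = NULL, gpr_path = NULL,
    dependency_path = NULL, expression_path = NULL, cnv_path = NULL,
    mutation_path = NULL, annotation_path = NULL,
    # stage toggles
    media_analysis = TRUE, correlation_analysis = TRUE, modeling = TRUE,
    # media pair compared throughout
    medium_a = "DMEM", medium_b = "RPMI",
    # per-stage variability thresholds (SD units)
    k_media = 6, k_correlation = 4, k_modeling = 2,
    # network parameters
    currency_fraction = 0.01, neighbor_cap = 50L, exclude_genes = NULL,
    drop_exchange = FALSE,
    # statistics
    fdr_threshold = 0.05, lineage_min = 10L,
    shuffled_set_repetitions = 1000L, permutation_repetitions = 25000L,
    shuffled_related_repetitions = 100L, run_shuffled_related = FALSE,
    include_lineage = TRUE, include_oncogene_cnv = FALSE, min_lines = 30L,
    n_trees = 100L, min_leaf = 5L,
    # execution
    seed = 1L, out_dir = "metdep_out", threads = 1L
  )
}

#' Build and validate a pipeline configuration
#'
#' Start from the defaults (the thresholds the analysis stages are defined
#' with: variability filters 6/4/2 SD, currency fraction 0.01, neighbor cap
#' 50, FDR 0.05, lineage minimum 10, shuffled-set null 1000, permutation
#' null 25000, shuffled-related control 100) and override with a JSON file
#' and/or named arguments; arguments win over the file. Unknown keys are
#' rejected. `threads` is accepted as a worker-parallelism contract: per-
#' gene seeds are derived from the base seed, so results are identical at
#' any thread count.
#'
#' @param config_path Optional JSON file of overrides.
#' @param ... Named overrides.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config_path = NULL, ...) {
  cfg <- default_config()
  apply_over <- function(cfg, over, origin) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration key(s) from ", origin, ": ",
           paste(unknown, collapse = ", "))
    }
    cfg[names(over)] <- over
    cfg
  }
  if (!is.null(config_path)) {
    cfg <- apply_over(cfg, jsonlite::read_json(config_path, simplifyVector = TRUE),
                      config_path)
  }
  over <- list(...)
  if (length(over)) cfg <- apply_over(cfg, over, "arguments")
  with(cfg, stopifnot(k_media > 0, k_correlation > 0, k_modeling > 0,
                      currency_fraction > 0, currency_fraction < 1,
                      neighbor_cap >= 1, fdr_threshold > 0, lineage_min >= 1,
                      shuffled_set_repetitions >= 1,
                      permutation_repetitions >= 1, threads >= 1,
                      n_trees >= 1, min_leaf >= 1))
  structure(cfg, class = c("pipeline_config", "list"))
}

write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", na = "NA")
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates model reading, relatedness extraction, screen loading and
#' the three analysis stages (media association with confounder controls;
#' expression correlations with related genes plus shuffled-set nulls;
#' permutation-calibrated dependency models), writing one TSV/JSON per
#' result plus a run manifest into `config$out_dir`. A failure inside a
#' stage aborts with a stage-named error; outputs of completed stages are
#' preserved on disk.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list (the report bundle) with the per-stage objects
#'   and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  bundle <- list(config = config)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  bundle$model <- stage("model_io", {
    if (!is.null(config$sbml_path)) read_sbml(config$sbml_path)
    else if (!is.null(config$reactions_path)) {
      read_tabular_model(config$reactions_path, config$gpr_path)
    } else stop("no model input configured (sbml_path or reactions_path)")
  })

  bundle$relatedness <- stage("neighbors", {
    rel <- build_relatedness(
      bundle$model, currency_fraction = config$currency_fraction,
      cap = config$neighbor_cap,
      exclude = config$exclude_genes %||% default_excluded_genes(bundle$model$genes),
      drop_exchange = config$drop_exchange)
    write_relatedness_tsv(rel, file.path(out, "relatedness.tsv"))
    write_relatedness_gmt(rel, file.path(out, "relatedness.gmt"))
    rel
  })

  bundle$dataset <- stage("screen_data", {
    load_screen(config$dependency_path, config$expression_path,
                config$cnv_path, config$mutation_path,
                config$annotation_path,
                metabolic_genes = bundle$model$genes)
  })
  ds <- bundle$dataset
  metabolic <- ds$metabolic_genes
  non_metabolic <- setdiff(rownames(ds$dependency), metabolic)

  if (isTRUE(config$media_analysis)) {
    bundle$media <- stage("media_analysis", {
      keep_m <- intersect(variability_filter(ds$dependency, config$k_media),
                          metabolic)
      keep_o <- intersect(variability_filter(ds$dependency, config$k_media),
                          non_metabolic)
      res_m <- media_association(ds, keep_m, config$medium_a, config$medium_b)
      res_o <- if (length(keep_o)) {
        media_association(ds, keep_o, config$medium_a, config$medium_b)
      } else res_m[0, ]
      partial <- media_partial_association(ds, keep_m, config$medium_a,
                                           config$medium_b, "culture_type")
      robust <- lineage_robustness(ds, keep_m, config$medium_a,
                                   config$medium_b,
                                   alpha = config$fdr_threshold,
                                   min_lines = config$lineage_min)
      comparison <- compare_pvalue_distributions(res_m$fdr_p, res_o$fdr_p)
      write_tsv(rbind(cbind(res_m, group = "metabolic"),
                      cbind(res_o, group = "non_metabolic")),
                file.path(out, "media_association.tsv"))
      write_tsv(partial, file.path(out, "media_partial_culture.tsv"))
      write_tsv(data.frame(gene = names(robust), lineage_robust = unname(robust)),
                file.path(out, "media_lineage_robust.tsv"))
      list(metabolic = res_m, non_metabolic = res_o, partial = partial,
           lineage_robust = robust, distribution_comparison = comparison)
    })
  }

  if (isTRUE(config$correlation_analysis)) {
    bundle$correlation <- stage("correlation_analysis", {
      keep <- intersect(variability_filter(ds$dependency, config$k_correlation),
                        metabolic)
      res <- list()
      for (mode in c("self", "isozyme", "neighbor")) {
        rr <- related_expression_correlations(ds, bundle$relatedness, mode,
                                              genes = keep,
                                              alpha = config$fdr_threshold)
        res[[mode]] <- rr
        write_tsv(rr, file.path(out, sprintf("expr_correlation_%s.tsv", mode)))
      }
      res$sign_tests <- lapply(res[c("self", "isozyme", "neighbor")],
                               sign_fraction_test,
                               alpha = config$fdr_threshold)
      res$nulls <- lapply(stats::setNames(nm = c("isozyme", "neighbor")),
        function(mode) {
          shuffled_set_null(ds, bundle$relatedness, mode,
                            repetitions = config$shuffled_set_repetitions,
                            genes = keep, alpha = config$fdr_threshold,
                            seed = derive_seed(config$seed, 311L))
        })
      jsonlite::write_json(res$nulls, file.path(out, "shuffled_set_null.json"),
                           auto_unbox = TRUE, digits = NA)
      res
    })
  }

  if (isTRUE(config$modeling)) {
    bundle$models <- stage("modeling", {
      genes <- intersect(variability_filter(ds$dependency, config$k_modeling),
                         metabolic)
      models <- suppressMessages(fit_dependency_models(
        ds, bundle$relatedness, genes = genes, n_trees = config$n_trees,
        min_leaf = config$min_leaf, include_lineage = config$include_lineage,
        include_oncogene_cnv = config$include_oncogene_cnv,
        min_lineage = config$lineage_min, min_lines = config$min_lines,
        seed = derive_seed(config$seed, 401L)))
      null_ps <- permutation_null(
        ds, bundle$relatedness, genes = models$gene,
        repetitions = config$permutation_repetitions,
        n_trees = config$n_trees, min_leaf = config$min_leaf,
        include_lineage = config$include_lineage,
        include_oncogene_cnv = config$include_oncogene_cnv,
        min_lineage = config$lineage_min, min_lines = config$min_lines,
        seed = derive_seed(config$seed, 402L))
      models <- empirical_significance(models, null_ps,
                                       alpha = config$fdr_threshold)
      categories <- categorize_top_features(models)
      write_tsv(as.data.frame(models), file.path(out, "dependency_models.tsv"))
      write_tsv(categories$categories, file.path(out, "feature_categories.tsv"))
      write_tsv(categories$features, file.path(out, "feature_breakdown.tsv"))
      res <- list(models = models, null_ps = null_ps, categories = categories)
      if (isTRUE(config$run_shuffled_related)) {
        res$shuffled_related <- shuffled_related_control(
          ds, bundle$relatedness, genes = models$gene, null_ps = null_ps,
          repetitions = config$shuffled_related_repetitions,
          alpha = config$fdr_threshold,
          seed = derive_seed(config$seed, 403L),
          n_trees = config$n_trees, min_leaf = config$min_leaf,
          include_lineage = config$include_lineage,
          min_lineage = config$lineage_min, min_lines = config$min_lines)
        jsonlite::write_json(res$shuffled_related,
                             file.path(out, "shuffled_related_control.json"),
                             auto_unbox = TRUE, digits = NA)
      }
      res
    })
  }

  manifest <- list(
    package = "metdep",
    version = as.character(utils::packageVersion("metdep")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config = unclass(config),
    stage_seconds = timings
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  bundle$manifest <- manifest
  invisible(bundle)
}

#' Summarize a pipeline report bundle
#'
#' Markdown summary of per-stage gene counts and significant fractions,
#' the feature-category prevalence table and pointers to the written
#' files. Missing stages are noted rather than failing.
#'
#' @param bundle The list returned by [run_pipeline()].
#' @return Character vector of markdown lines, invisibly; also printed.
#' @export
summarize_run <- function(bundle) {
  alpha <- bundle$config$fdr_threshold
  lines <- c("# metdep run summary", "",
             sprintf("- seed: %s; output: %s", bundle$config$seed,
                     bundle$config$out_dir))
  if (!is.null(bundle$media)) {
    m <- bundle$media$metabolic
    o <- bundle$media$non_metabolic
    sig <- function(d) sum(!is.na(d$fdr_p) & d$fdr_p < alpha)
    lines <- c(lines, "", "## Media association",
      sprintf("- metabolic genes tested: %d; significant at FDR %.2f: %d (%.1f%%)",
              nrow(m), alpha, sig(m), 100 * sig(m) / max(1, nrow(m))),
      sprintf("- non-metabolic genes tested: %d; significant: %d (%.1f%%)",
              nrow(o), sig(o), 100 * sig(o) / max(1, nrow(o))),
      sprintf("- lineage-robust media genes: %d of %d",
              sum(bundle$media$lineage_robust),
              length(bundle$media$lineage_robust)),
      sprintf("- metabolic vs non-metabolic p-value distributions: rank-sum p = %.3g",
              bundle$media$distribution_comparison$p))
  } else lines <- c(lines, "", "## Media association", "- stage not run")
  if (!is.null(bundle$correlation)) {
    lines <- c(lines, "", "## Expression correlations")
    for (mode in c("self", "isozyme", "neighbor")) {
      rr <- bundle$correlation[[mode]]
      expl <- attr(rr, "explained")
      lines <- c(lines, sprintf(
        "- %s: %d pairs tested; explained genes: %d of %d (%.1f%%)",
        mode, nrow(rr), sum(expl), length(expl),
        100 * mean(expl %||% NA)))
    }
    for (mode in c("isozyme", "neighbor")) {
      nl <- bundle$correlation$nulls[[mode]]
      lines <- c(lines, sprintf(
        "- shuffled-set null (%s): observed %.3f, empirical p = %.4f",
        mode, nl$observed_fraction, nl$empirical_p))
    }
  } else lines <- c(lines, "", "## Expression correlations", "- stage not run")
  if (!is.null(bundle$models)) {
    mm <- bundle$models$models
    lines <- c(lines, "", "## Dependency models",
      sprintf("- genes modeled: %d; significant at FDR %.2f: %d (%.1f%%)",
              nrow(mm), alpha, sum(mm$significant),
              100 * mean(mm$significant)),
      sprintf("- mean OOB Pearson r of significant models: %.3f",
              mean(mm$oob_r[mm$significant])),
      sprintf("- mean OOB Spearman r of significant models: %.3f",
              mean(mm$spearman_r[mm$significant])),
      "", "category | fraction top | fraction top5", "--- | --- | ---")
    ct <- bundle$models$categories$categories
    lines <- c(lines, sprintf("%s | %.2f | %.2f", ct$category,
                              ct$fraction_top, ct$fraction_top5))
  } else lines <- c(lines, "", "## Dependency models", "- stage not run")
  lines <- c(lines, "", sprintf("Files under %s: %s", bundle$config$out_dir,
    paste(sort(list.files(bundle$config$out_dir)), collapse = ", ")))
  cat(lines, sep = "\n")
  invisible(lines)
}
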