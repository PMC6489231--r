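# Per-gene predictive models of dependency scores: feature assembly,
# forest fitting, permutation-null calibration, importance ranking and
# category summaries.

FEATURE_CATEGORIES <- c("self_exp", "self_cnv", "iso_exp", "iso_cnv",
                        "related_exp", "related_cnv", "mutation", "media",
                        "lineage")

#' Assemble the feature table for one gene's dependency model
#'
#' Columns: the gene's own expression and copy number; expression and copy
#' number of each isozyme and each neighboring enzyme with measurements;
#' one binary column per oncogene mutation; one-hot media columns; and,
#' when `include_lineage`, one-hot columns for lineages with at least
#' `min_lineage` cell lines (smaller lineages pool into `lineage.other`).
#' Oncogene copy number is excluded by default (adding it did not improve
#' the models; `include_oncogene_cnv` re-enables it). Missing continuous
#' values are mean-imputed per column; constant columns are dropped with a
#' message.
#'
#' @param gene Target gene id.
#' @param dataset A [screen_dataset()].
#' @param relatedness A `relatedness_map`; a gene absent from it proceeds
#'   with self + mutation + media (+ lineage) features only, with a message.
#' @param include_lineage Add lineage indicator columns (default `TRUE`).
#' @param include_oncogene_cnv Add oncogene copy-number columns (default
#'   `FALSE`).
#' @param min_lineage Minimum lineage size for its own column (default 10).
#' @return List with `matrix` (cell lines x features), `categories` (named
#'   character vector feature -> category) and `dropped` (constant columns
#'   removed).
#' @export
assemble_features <- function(gene, dataset, relatedness,
                              include_lineage = TRUE,
                              include_oncogene_cnv = FALSE,
                              min_lineage = 10L) {
  lines <- dataset$cell_lines
  cols <- list()
  cats <- character(0)
  add <- function(name, values, category) {
    v <- as.numeric(values)
    if (anyNA(v)) {
      mu <- mean(v, na.rm = TRUE)
      v[is.na(v)] <- if (is.nan(mu)) 0 else mu
    }
    cols[[name]] <<- v
    cats[name] <<- category
  }
  if (gene %in% rownames(dataset$expression)) {
    add("self_exp", dataset$expression[gene, ], "self_exp")
  }
  if (gene %in% rownames(dataset$cnv)) {
    add("self_cnv", dataset$cnv[gene, ], "self_cnv")
  }
  in_map <- gene %in% names(relatedness$neighbors) ||
    gene %in% names(relatedness$isozymes)
  if (!in_map) {
    message("gene ", gene, " absent from relatedness map; ",
            "using self, mutation and media features only")
  }
  iso <- setdiff(relatedness$isozymes[[gene]], gene)
  nbr <- setdiff(setdiff(relatedness$neighbors[[gene]], gene), iso)
  for (partner in iso) {
    if (partner %in% rownames(dataset$expression)) {
      add(paste0("iso_exp.", partner), dataset$expression[partner, ], "iso_exp")
    }
    if (partner %in% rownames(dataset$cnv)) {
      add(paste0("iso_cnv.", partner), dataset$cnv[partner, ], "iso_cnv")
    }
  }
  for (partner in nbr) {
    if (partner %in% rownames(dataset$expression)) {
      add(paste0("rel_exp.", partner), dataset$expression[partner, ], "related_exp")
    }
    if (partner %in% rownames(dataset$cnv)) {
      add(paste0("rel_cnv.", partner), dataset$cnv[partner, ], "related_cnv")
    }
  }
  for (onc in rownames(dataset$mutations)) {
    add(paste0("mut.", onc), dataset$mutations[onc, ], "mutation")
    if (include_oncogene_cnv && onc %in% rownames(dataset$cnv)) {
      add(paste0("onc_cnv.", onc), dataset$cnv[onc, ], "related_cnv")
    }
  }
  for (m in sort(unique(dataset$annotations$medium))) {
    add(paste0("media.", m), as.numeric(dataset$annotations$medium == m), "media")
  }
  if (include_lineage) {
    keep <- qualifying_lineages(dataset, min_lineage)
    lin <- dataset$annotations$lineage
    pooled <- ifelse(lin %in% keep, lin, "other")
    for (l in sort(unique(pooled))) {
      add(paste0("lineage.", l), as.numeric(pooled == l), "lineage")
    }
  }
  X <- do.call(cbind, cols)
  if (is.null(X)) stop("no features available for gene ", gene)
  rownames(X) <- lines
  constant <- apply(X, 2L, function(v) max(v) == min(v))
  if (any(constant)) {
    message("dropping ", sum(constant), " constant feature column(s) for ",
            gene, ": ", paste(utils::head(colnames(X)[constant], 5), collapse = ", "))
  }
  keep_cols <- colnames(X)[!constant]
  list(matrix = X[, keep_cols, drop = FALSE],
       categories = cats[keep_cols],
       dropped = colnames(X)[constant])
}

# Deterministic per-(seed, index) sub-seed, < 2^31 and order-independent,
# so worker parallelism over genes cannot change results.
derive_seed <- function(seed, index) {
  ((as.numeric(seed) %% 65536) * 32749 + as.numeric(index) * 7919 + 1) %% 2147483647
}

#' Fit permutation-calibratable dependency models for a gene set
#'
#' For each gene (those passing the modeling variability filter, k = 2, and
#' with at least `min_lines` non-missing dependency scores): assemble the
#' feature table, fit the forest (100 trees, min leaf 5), record the
#' out-of-bag Pearson goodness of fit, rank features by OOB permutation
#' importance, refit on the positive-importance features, and record the
#' refit model's top features. Pearson drives significance; the Spearman
#' analogue is reported alongside.
#'
#' @param dataset A [screen_dataset()].
#' @param relatedness A `relatedness_map`.
#' @param genes Genes to model; default: metabolic genes passing
#'   [variability_filter()] at `k`.
#' @param k Variability filter threshold (default 2).
#' @param n_trees,min_leaf Forest parameters (defaults 100 and 5).
#' @param include_lineage,include_oncogene_cnv,min_lineage Passed to
#'   [assemble_features()].
#' @param min_lines Minimum non-missing dependency scores (default 30).
#' @param seed Base seed; each gene uses a derived sub-seed.
#' @return data.frame (class `metdep_models`) with one row per modeled
#'   gene: `gene`, `oob_r`, `oob_p`, `spearman_r`, `n_features`,
#'   `n_features_final`, `top_feature`, `top_category`, `top5`
#'   (semicolon-joined `feature|category`), `unexplainable`, `seed`.
#'   Attribute `"importances"`: named list of per-gene importance tables.
#' @export
fit_dependency_models <- function(dataset, relatedness, genes = NULL, k = 2,
                                  n_trees = 100L, min_leaf = 5L,
                                  include_lineage = TRUE,
                                  include_oncogene_cnv = FALSE,
                                  min_lineage = 10L, min_lines = 30L,
                                  seed = 1L) {
  if (is.null(genes)) {
    genes <- intersect(dataset$metabolic_genes,
                       variability_filter(dataset$dependency, k))
  }
  rows <- list()
  imps <- list()
  for (i in seq_along(genes)) {
    g <- genes[i]
    y_all <- dataset$dependency[g, ]
    keep <- !is.na(y_all)
    if (sum(keep) < min_lines) {
      message("gene ", g, ": fewer than ", min_lines,
              " scored cell lines; skipped")
      next
    }
    feats <- assemble_features(g, dataset, relatedness,
                               include_lineage = include_lineage,
                               include_oncogene_cnv = include_oncogene_cnv,
                               min_lineage = min_lineage)
    X <- feats$matrix[keep, , drop = FALSE]
    y <- y_all[keep]
    gseed <- derive_seed(seed, i)
    fit <- fit_forest(X, y, n_trees = n_trees, min_leaf = min_leaf,
                      seed = gseed, importance = TRUE)
    gof <- oob_goodness_of_fit(fit, y)
    ref <- importance_and_refit(fit, X, y, categories = feats$categories)
    top5 <- if (length(ref$top5)) {
      paste(paste0(ref$top5, "|", feats$categories[ref$top5]), collapse = ";")
    } else ""
    rows[[g]] <- data.frame(
      gene = g, oob_r = gof$r, oob_p = gof$p, spearman_r = gof$spearman_r,
      n_features = ncol(X), n_features_final = length(ref$kept),
      top_feature = ref$top_feature,
      top_category = if (is.na(ref$top_feature)) NA_character_ else
        unname(feats$categories[ref$top_feature]),
      top5 = top5, unexplainable = ref$unexplainable, seed = gseed,
      stringsAsFactors = FALSE)
    imps[[g]] <- ref$importances
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    gene = character(0), oob_r = numeric(0), oob_p = numeric(0),
    spearman_r = numeric(0), n_features = integer(0),
    n_features_final = integer(0), top_feature = character(0),
    top_category = character(0), top5 = character(0),
    unexplainable = logical(0), seed = numeric(0))
  rownames(out) <- NULL
  structure(out, importances = imps, class = c("metdep_models", "data.frame"))
}

#' Permutation null for the model goodness of fit
#'
#' Each repetition draws a gene uniformly from the modeled set, permutes its
#' dependency scores across cell lines, fits the same forest on the gene's
#' (unchanged) feature table, and records the out-of-bag Pearson p-value.
#' The collected p-values form the empirical null for
#' [empirical_significance()]. Feature tables are assembled once per gene
#' and cached (permuting the response never changes them). The pipeline
#' default is 25000 repetitions; tests use at most 1000.
#'
#' @param dataset A [screen_dataset()].
#' @param relatedness A `relatedness_map`.
#' @param genes The modeled gene set (the null pool).
#' @param repetitions Number of repetitions (>= 100 recommended).
#' @param n_trees,min_leaf,include_lineage,include_oncogene_cnv,min_lineage,min_lines
#'   As in [fit_dependency_models()].
#' @param seed Integer seed.
#' @return Sorted numeric vector of null Pearson p-values (repetitions with
#'   a degenerate fit are recorded as 1).
#' @export
permutation_null <- function(dataset, relatedness, genes,
                             repetitions = 25000L, n_trees = 100L,
                             min_leaf = 5L, include_lineage = TRUE,
                             include_oncogene_cnv = FALSE,
                             min_lineage = 10L, min_lines = 30L, seed = 1L) {
  stopifnot(repetitions >= 1L, length(genes) >= 1L)
  cache <- lapply(stats::setNames(nm = genes), function(g) {
    y_all <- dataset$dependency[g, ]
    keep <- !is.na(y_all)
    if (sum(keep) < min_lines) return(NULL)
    feats <- suppressMessages(assemble_features(
      g, dataset, relatedness, include_lineage = include_lineage,
      include_oncogene_cnv = include_oncogene_cnv, min_lineage = min_lineage))
    list(X = feats$matrix[keep, , drop = FALSE], y = y_all[keep])
  })
  cache <- Filter(Negate(is.null), cache)
  if (length(cache) == 0L) stop("no modelable gene in the null pool")
  rng <- local_rng(seed)
  on.exit(rng$restore())
  ps <- numeric(repetitions)
  for (rep in seq_len(repetitions)) {
    entry <- cache[[sample.int(length(cache), 1L)]]
    y_perm <- entry$y[sample.int(length(entry$y))]
    fit <- fit_forest(entry$X, y_perm, n_trees = n_trees, min_leaf = min_leaf,
                      seed = derive_seed(seed, rep), importance = FALSE)
    gof <- oob_goodness_of_fit(fit, y_perm)
    ps[rep] <- if (gof$ok) gof$p else 1
  }
  sort(ps)
}

#' Empirical significance of dependency models
#'
#' For each model, the empirical p-value is the add-one fraction of null
#' Pearson p-values at or below the model's observed p:
#' `(1 + #\{null <= observed\}) / (N + 1)`; BH-FDR across the modeled
#' genes; significant means `fdr_p < alpha`. Models with no usable
#' goodness of fit get `NA` and are excluded from the correction.
#'
#' @param models A `metdep_models` data.frame from
#'   [fit_dependency_models()].
#' @param null_ps Numeric vector of null p-values from
#'   [permutation_null()].
#' @param alpha Significance cutoff (default 0.05).
#' @return The models data.frame with `empirical_p`, `fdr_p` and
#'   `significant` columns added (attributes preserved).
#' @export
empirical_significance <- function(models, null_ps, alpha = 0.05) {
  stopifnot(length(null_ps) >= 1L)
  null_sorted <- sort(null_ps)
  n <- length(null_sorted)
  emp <- vapply(models$oob_p, function(p) {
    if (is.na(p)) return(NA_real_)
    (1 + sum(null_sorted <= p)) / (n + 1)
  }, numeric(1))
  models$empirical_p <- emp
  models$fdr_p <- bh_fdr(emp)
  models$significant <- !is.na(models$fdr_p) & models$fdr_p < alpha &
    !models$unexplainable
  models
}

#' Shuffled related-set control for the modeling stage
#'
#' Re-runs the whole modeling stage with each gene's related sets
#' (neighbors and isozymes) replaced by equal-size random gene sets drawn
#' from the expression-measured genes, and records the fraction of
#' significant models per repetition. Significance is judged against the
#' same permutation null as the real analysis. The pipeline default is 100
#' repetitions; tests use at most 20.
#'
#' @param dataset A [screen_dataset()].
#' @param relatedness The real `relatedness_map` (supplies the set sizes).
#' @param genes The modeled gene set.
#' @param null_ps Null p-values from [permutation_null()].
#' @param repetitions Number of shuffles.
#' @param alpha Significance cutoff (default 0.05).
#' @param seed Integer seed.
#' @param ... Passed to [fit_dependency_models()].
#' @return List with `observed_fraction` (real relatedness),
#'   `control_fractions` (one per repetition) and `empirical_p` (add-one).
#' @export
shuffled_related_control <- function(dataset, relatedness, genes, null_ps,
                                     repetitions = 100L, alpha = 0.05,
                                     seed = 1L, ...) {
  stopifnot(repetitions >= 1L)
  real <- empirical_significance(
    suppressMessages(fit_dependency_models(dataset, relatedness, genes = genes,
                                           seed = seed, ...)),
    null_ps, alpha)
  observed <- mean(real$significant)
  pool <- rownames(dataset$expression)
  rng <- local_rng(seed)
  on.exit(rng$restore())
  fractions <- numeric(repetitions)
  for (rep in seq_len(repetitions)) {
    shuffled <- relatedness
    for (field in c("neighbors", "isozymes")) {
      sets <- relatedness[[field]]
      shuffled[[field]] <- stats::setNames(lapply(names(sets), function(g) {
        k <- length(sets[[g]])
        if (k == 0L) character(0)
        else sample(setdiff(pool, g), min(k, length(pool) - 1L))
      }), names(sets))
    }
    ctl <- empirical_significance(
      suppressMessages(fit_dependency_models(dataset, shuffled, genes = genes,
                                             seed = derive_seed(seed, rep), ...)),
      null_ps, alpha)
    fractions[rep] <- mean(ctl$significant)
  }
  list(observed_fraction = observed, control_fractions = fractions,
       empirical_p = (1 + sum(fractions >= observed)) / (repetitions + 1))
}

#' Summarize top-feature categories across significant models
#'
#' For each feature category (and individually for each mutation, media and
#' lineage feature), the fraction of significant models in which it is the
#' top-ranked feature and in which it appears among the top 5. Fractions
#' are over significant models only; with no significant model the summary
#' is empty.
#'
#' @param models A `metdep_models` data.frame carrying `significant`,
#'   `top_feature`/`top_category` and `top5` columns.
#' @return List with `categories` (data.frame `category`, `fraction_top`,
#'   `fraction_top5`) and `features` (the same per individual mutation /
#'   media / lineage feature).
#' @export
categorize_top_features <- function(models) {
  sig <- models[!is.na(models$significant) & models$significant, , drop = FALSE]
  n <- nrow(sig)
  empty <- data.frame(category = character(0), fraction_top = numeric(0),
                      fraction_top5 = numeric(0))
  if (n == 0L) return(list(categories = empty, features = empty))
  top5_sets <- strsplit(sig$top5, ";", fixed = TRUE)
  split5 <- lapply(top5_sets, function(entries) {
    entries <- entries[nzchar(entries)]
    parts <- strsplit(entries, "|", fixed = TRUE)
    data.frame(feature = vapply(parts, `[`, character(1), 1),
               category = vapply(parts, `[`, character(1), 2),
               stringsAsFactors = FALSE)
  })
  cats <- data.frame(category = FEATURE_CATEGORIES, stringsAsFactors = FALSE)
  cats$fraction_top <- vapply(cats$category, function(cc) {
    mean(sig$top_category == cc, na.rm = TRUE)
  }, numeric(1))
  cats$fraction_top5 <- vapply(cats$category, function(cc) {
    mean(vapply(split5, function(d) cc %in% d$category, logical(1)))
  }, numeric(1))
  feat_all <- unique(unlist(lapply(split5, function(d) {
    d$feature[d$category %in% c("mutation", "media", "lineage")]
  })))
  feats <- if (length(feat_all)) {
    data.frame(
      category = sort(feat_all),
      fraction_top = vapply(sort(feat_all), function(f) {
        mean(sig$top_feature == f, na.rm = TRUE)
      }, numeric(1)),
      fraction_top5 = vapply(sort(feat_all), function(f) {
        mean(vapply(split5, function(d) f %in% d$feature, logical(1)))
      }, numeric(1)),
      stringsAsFactors = FALSE)
  } else empty
  rownames(feats) <- NULL
  list(categories = cats, features = feats)
}
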