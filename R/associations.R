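# Association analyses: media effects on dependency scores (with confounder
# controls) and correlations with the expression of functionally related
# genes, each calibrated against shuffled nulls.

#' Per-gene association between dependency score and culture medium
#'
#' For each gene, the dependency scores of cell lines grown in `medium_a`
#' are compared with those grown in `medium_b` by a two-sided rank-sum test;
#' p-values are BH-FDR corrected across the tested gene set. Call once for
#' metabolic and once for non-metabolic genes to correct the two families
#' separately. Direction reports which medium has the lower (more
#' essential) median score.
#'
#' @param dataset A [screen_dataset()].
#' @param genes Genes to test (rows of the dependency matrix).
#' @param medium_a,medium_b Media labels present in the annotations.
#' @return data.frame with columns `gene`, `test`, `partner`, `statistic`,
#'   `direction` (-1: more essential in `medium_a`; +1: in `medium_b`;
#'   `NA`: tie), `p`, `fdr_p`.
#' @export
media_association <- function(dataset, genes, medium_a, medium_b) {
  med <- dataset$annotations$medium
  for (m in c(medium_a, medium_b)) {
    if (!m %in% med) stop("unknown medium label: ", m)
  }
  in_a <- med == medium_a
  in_b <- med == medium_b
  res <- lapply(genes, function(g) {
    sc <- dataset$dependency[g, ]
    ht <- rank_sum_test(sc[in_a], sc[in_b])
    dir <- if (!ht$ok) NA_real_ else {
      d <- stats::median(sc[in_a], na.rm = TRUE) - stats::median(sc[in_b], na.rm = TRUE)
      if (d < 0) -1 else if (d > 0) 1 else NA_real_
    }
    data.frame(gene = g, test = "media_wilcoxon", partner = "",
               statistic = ht$statistic, direction = dir, p = ht$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr_p <- bh_fdr(out$p)
  out
}

# Indicator vector of medium_a vs medium_b over the dataset's cell lines;
# lines in neither medium are NA (excluded pairwise downstream).
media_indicator <- function(dataset, medium_a, medium_b) {
  med <- dataset$annotations$medium
  ind <- rep(NA_real_, length(med))
  ind[med == medium_a] <- 1
  ind[med == medium_b] <- 0
  ind
}

#' Partial media association controlling for a binary/categorical covariate
#'
#' For each gene, the Spearman partial correlation between its dependency
#' scores and the binary media indicator (`medium_a` = 1, `medium_b` = 0),
#' controlling for the given covariate; BH-FDR across the tested genes. Used
#' with `control = "culture_type"` to ask whether the adherent/suspension
#' split explains away the media association.
#'
#' @param dataset A [screen_dataset()].
#' @param genes Genes to test.
#' @param medium_a,medium_b Media labels.
#' @param control Either the string `"culture_type"` or a numeric covariate
#'   vector over the dataset's cell lines.
#' @return data.frame with columns `gene`, `test`, `partner`, `statistic`,
#'   `direction`, `p`, `fdr_p`, `ok`.
#' @export
media_partial_association <- function(dataset, genes, medium_a, medium_b,
                                      control = "culture_type") {
  ind <- media_indicator(dataset, medium_a, medium_b)
  test_name <- "partial_media_custom"
  if (identical(control, "culture_type")) {
    control <- as.numeric(dataset$annotations$culture_type ==
                            dataset$annotations$culture_type[1])
    test_name <- "partial_media_culture"
  }
  res <- lapply(genes, function(g) {
    ps <- partial_spearman(dataset$dependency[g, ], ind, control)
    data.frame(gene = g, test = test_name, partner = "",
               statistic = ps$r, direction = ifelse(is.na(ps$r), NA_real_, sign(ps$r)),
               p = ps$p, ok = ps$ok, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr_p <- bh_fdr(out$p)
  out
}

# Lineages qualifying as covariates: at least `min_lines` cell lines.
qualifying_lineages <- function(dataset, min_lines = 10L) {
  tab <- table(dataset$annotations$lineage)
  names(tab)[tab >= min_lines]
}

#' Lineage robustness of media associations
#'
#' For every qualifying cancer lineage (>= `min_lines` cell lines), the
#' media association of each gene is re-tested as a partial Spearman
#' correlation controlling for that lineage's indicator, with BH-FDR across
#' genes within each control family. A gene is lineage-robust when it stays
#' significant under every qualifying control. A constant indicator (after
#' pairwise missing removal) cannot be controlled for; such controls fall
#' back to the unadjusted correlation, with a message. When no lineage
#' qualifies the verdict is vacuously `TRUE`.
#'
#' @param dataset A [screen_dataset()].
#' @param genes Genes to assess.
#' @param medium_a,medium_b Media labels.
#' @param alpha FDR significance cutoff (default 0.05).
#' @param min_lines Minimum lineage size (default 10).
#' @return Named logical vector over `genes`, with attribute `"detail"`: a
#'   data.frame of per-(gene, lineage) partial results.
#' @export
lineage_robustness <- function(dataset, genes, medium_a, medium_b,
                               alpha = 0.05, min_lines = 10L) {
  ind <- media_indicator(dataset, medium_a, medium_b)
  lineages <- qualifying_lineages(dataset, min_lines)
  robust <- stats::setNames(rep(TRUE, length(genes)), genes)
  detail <- list()
  if (length(lineages) == 0L) {
    message("no lineage with >= ", min_lines, " cell lines; verdict vacuously TRUE")
    return(structure(robust, detail = data.frame()))
  }
  for (lin in lineages) {
    z <- as.numeric(dataset$annotations$lineage == lin)
    ps <- lapply(genes, function(g) {
      x <- dataset$dependency[g, ]
      out <- partial_spearman(x, ind, z)
      if (!out$ok && identical(out$degenerate, "constant covariate")) {
        message("lineage ", lin, " constant after missing removal; ",
                "falling back to unadjusted correlation for gene ", g)
        sp <- spearman_cor(x, ind)
        out <- list(r = sp$r, p = sp$p, n = sp$n, ok = sp$ok, degenerate = "fallback")
      }
      out
    })
    p <- vapply(ps, `[[`, numeric(1), "p")
    fdr <- bh_fdr(p)
    sig <- !is.na(fdr) & fdr < alpha
    robust <- robust & sig
    detail[[lin]] <- data.frame(gene = genes, test = "partial_media_lineage",
                                partner = lin,
                                statistic = vapply(ps, `[[`, numeric(1), "r"),
                                p = p, fdr_p = fdr, significant = sig,
                                stringsAsFactors = FALSE)
  }
  structure(robust, detail = do.call(rbind, detail))
}

#' Correlate dependency scores with expression of related genes
#'
#' For `mode = "self"`, one Spearman correlation per gene between its
#' dependency scores and its own expression. For `"isozyme"`/`"neighbor"`,
#' one correlation per (gene, partner) pair over the gene's related set,
#' with BH-FDR across all tested pairs of the mode; a gene is "explained"
#' when at least one of its partners is significant after correction.
#' Partners without expression measurements, or with constant expression,
#' are skipped.
#'
#' @param dataset A [screen_dataset()].
#' @param relatedness A `relatedness_map` from [build_relatedness()] (not
#'   needed for `mode = "self"`).
#' @param mode `"self"`, `"isozyme"` or `"neighbor"`.
#' @param genes Genes to test; default: metabolic genes passing no further
#'   filter (callers apply the stage's variability filter first).
#' @param alpha FDR cutoff for the per-gene explained flag (default 0.05).
#' @return data.frame with columns `gene`, `test`, `partner`, `statistic`
#'   (Spearman r), `direction`, `p`, `fdr_p`, plus attribute `"explained"`:
#'   named logical per gene.
#' @export
related_expression_correlations <- function(dataset, relatedness = NULL,
                                            mode = c("self", "isozyme", "neighbor"),
                                            genes = dataset$metabolic_genes,
                                            alpha = 0.05) {
  mode <- match.arg(mode)
  pairs <- switch(mode,
    self = data.frame(gene = genes, partner = genes, stringsAsFactors = FALSE),
    isozyme = relatedness_pairs(relatedness$isozymes, genes),
    neighbor = relatedness_pairs(relatedness$neighbors, genes)
  )
  test_name <- paste0("expr_", mode)
  if (nrow(pairs) == 0L) {
    out <- data.frame(gene = character(0), test = character(0),
                      partner = character(0), statistic = numeric(0),
                      direction = numeric(0), p = numeric(0), fdr_p = numeric(0))
    return(structure(out, explained = stats::setNames(logical(0), character(0))))
  }
  pairs <- pairs[pairs$partner %in% rownames(dataset$expression), , drop = FALSE]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    g <- pairs$gene[i]; partner <- pairs$partner[i]
    sp <- spearman_cor(dataset$dependency[g, ], dataset$expression[partner, ])
    if (!sp$ok) return(NULL)  # constant/short partner skipped
    data.frame(gene = g, test = test_name, partner = partner,
               statistic = sp$r, direction = sign(sp$r), p = sp$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), test = character(0),
                      partner = character(0), statistic = numeric(0),
                      direction = numeric(0), p = numeric(0))
  }
  out$fdr_p <- bh_fdr(out$p)
  explained <- vapply(stats::setNames(nm = unique(pairs$gene)), function(g) {
    any(out$gene == g & !is.na(out$fdr_p) & out$fdr_p < alpha)
  }, logical(1))
  structure(out, explained = explained)
}

relatedness_pairs <- function(sets, genes) {
  genes <- intersect(genes, names(sets))
  rows <- lapply(genes, function(g) {
    partners <- setdiff(sets[[g]], g)
    if (length(partners) == 0L) return(NULL)
    data.frame(gene = g, partner = partners, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(gene = character(0), partner = character(0)) else out
}

#' Shuffled related-set null for the explained-gene fraction
#'
#' Repeats the [related_expression_correlations()] analysis with each
#' gene's related set replaced by a uniformly random, equal-size set drawn
#' from the expression-measured genes, and compares the observed fraction
#' of explained genes against the null fractions with the add-one empirical
#' p-value `(1 + #\{null >= observed\}) / (repetitions + 1)`.
#'
#' @param dataset A [screen_dataset()].
#' @param relatedness A `relatedness_map`.
#' @param mode `"isozyme"` or `"neighbor"`.
#' @param repetitions Number of shuffles (pipeline default 1000; tests use
#'   fewer).
#' @param genes Genes to test (pre-filtered by the caller).
#' @param alpha FDR cutoff (default 0.05).
#' @param seed Integer seed for the shuffles.
#' @return List with `observed_fraction`, `null_fractions` (length
#'   `repetitions`), `empirical_p`.
#' @export
shuffled_set_null <- function(dataset, relatedness, mode = c("isozyme", "neighbor"),
                              repetitions = 1000L, genes = dataset$metabolic_genes,
                              alpha = 0.05, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(repetitions >= 1L)
  sets <- relatedness[[if (mode == "isozyme") "isozymes" else "neighbors"]]
  obs <- related_expression_correlations(dataset, relatedness, mode, genes, alpha)
  observed <- mean(attr(obs, "explained"))
  if (is.nan(observed)) observed <- 0
  pool <- rownames(dataset$expression)
  genes_here <- intersect(genes, names(sets))
  sizes <- lengths(sets[genes_here])
  null_fractions <- numeric(repetitions)
  rng <- local_rng(seed)
  for (rep in seq_len(repetitions)) {
    shuffled <- relatedness
    shuffled[[if (mode == "isozyme") "isozymes" else "neighbors"]] <-
      stats::setNames(lapply(seq_along(genes_here), function(i) {
        if (sizes[i] == 0L) character(0)
        else sample(setdiff(pool, genes_here[i]), min(sizes[i], length(pool) - 1L))
      }), genes_here)
    r <- related_expression_correlations(dataset, shuffled, mode, genes, alpha)
    frac <- mean(attr(r, "explained"))
    null_fractions[rep] <- if (is.nan(frac)) 0 else frac
  }
  rng$restore()
  list(observed_fraction = observed, null_fractions = null_fractions,
       empirical_p = (1 + sum(null_fractions >= observed)) / (repetitions + 1))
}

# Scoped RNG: set a seed, restore the caller's RNG state on $restore().
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
}
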