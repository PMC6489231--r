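# R interface to the bagged regression forest.

#' Fit a bagged regression forest with out-of-bag predictions
#'
#' Regression trees grown on bootstrap samples of size n; `mtry` features
#' tried per split (default a third of the available features, the standard
#' regression choice); leaves hold at least `min_leaf` bootstrap
#' observations. Out-of-bag (OOB) predictions — each sample predicted only
#' by trees whose bootstrap left it out — provide the internal goodness-of-
#' fit estimate; samples never out of bag (probability ~ 0.366^ntree) are
#' excluded from scoring.
#'
#' @param features Numeric matrix (cell lines x features) with column
#'   names, or a feature table from [assemble_features()].
#' @param y Numeric response (dependency scores), no missing values.
#' @param n_trees Number of trees (default 100).
#' @param min_leaf Minimum leaf size (default 5).
#' @param mtry Features tried per split; default `max(1, floor(p/3))`.
#' @param seed Integer seed; identical inputs and seed give identical
#'   forests on any platform.
#' @param importance Compute OOB permutation importance (default `TRUE`).
#' @return Object of class `metdep_forest`: list with `oob_pred`,
#'   `oob_count`, `importance` (data.frame: feature, raw mean OOB-MSE
#'   increase, sd across trees, scaled = mean/sd), `n`, `p`, and the call
#'   parameters.
#' @export
fit_forest <- function(features, y, n_trees = 100L, min_leaf = 5L,
                       mtry = NULL, seed = 1L, importance = TRUE) {
  X <- if (is.list(features) && !is.null(features$matrix)) features$matrix else features
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (anyNA(y)) stop("y contains missing values; drop them before fitting")
  if (anyNA(X)) stop("feature matrix contains missing values; impute first")
  if (ncol(X) == 0L) stop("zero usable features")
  if (stats::sd(y) == 0) stop("constant response: goodness of fit is degenerate")
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(X) / 3))
  fit <- .rf_fit_cpp(X, as.numeric(y), as.integer(n_trees),
                     as.integer(min_leaf), as.integer(mtry),
                     as.numeric(seed), isTRUE(importance))
  never_oob <- sum(fit$oob_count == 0L)
  if (never_oob > 0L) {
    message(never_oob, " sample(s) never out of bag; excluded from OOB scoring")
  }
  imp <- NULL
  if (importance) {
    scaled <- ifelse(fit$imp_sd > 0, fit$imp_mean / fit$imp_sd, fit$imp_mean)
    imp <- data.frame(feature = colnames(X), raw = fit$imp_mean,
                      sd = fit$imp_sd, scaled = scaled,
                      stringsAsFactors = FALSE)
  }
  structure(list(oob_pred = stats::setNames(fit$oob_pred, rownames(X)),
                 oob_count = fit$oob_count, importance = imp,
                 n = nrow(X), p = ncol(X), n_trees = n_trees,
                 min_leaf = min_leaf, mtry = mtry, seed = seed),
            class = "metdep_forest")
}

#' @export
print.metdep_forest <- function(x, ...) {
  cat(sprintf("<metdep_forest> %d trees, n=%d, p=%d, min_leaf=%d, mtry=%d\n",
              x$n_trees, x$n, x$p, x$min_leaf, x$mtry))
  invisible(x)
}

#' Out-of-bag goodness of fit
#'
#' Pearson correlation (with two-sided p) between out-of-bag predictions
#' and the observed response, the model-quality statistic the permutation
#' null calibrates. The Spearman analogue is also reported.
#'
#' @param oob_predictions Numeric vector of OOB predictions (`NA` for
#'   samples never out of bag) or a `metdep_forest`.
#' @param y Observed response.
#' @return List with `r`, `p`, `spearman_r`, `n`, `ok` (`FALSE` when fewer
#'   than 10 scored samples or a zero-variance vector).
#' @export
oob_goodness_of_fit <- function(oob_predictions, y) {
  if (inherits(oob_predictions, "metdep_forest")) {
    oob_predictions <- oob_predictions$oob_pred
  }
  keep <- stats::complete.cases(oob_predictions, y)
  pred <- oob_predictions[keep]; obs <- y[keep]
  n <- length(pred)
  if (n < 10L || stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    return(list(r = NA_real_, p = NA_real_, spearman_r = NA_real_, n = n, ok = FALSE))
  }
  r <- stats::cor(pred, obs)
  list(r = r, p = t_pvalue_for_r(r, n, df = n - 2L),
       spearman_r = stats::cor(rank(pred), rank(obs)), n = n, ok = TRUE)
}

#' Permutation importance, positive-importance refit
#'
#' Ranks features by out-of-bag permutation importance (mean OOB-MSE
#' increase under feature permutation, scaled by its standard deviation
#' across trees), keeps the features with strictly positive raw importance,
#' and refits the forest on those alone; the refit model supplies the final
#' importance ranking and the top features. A model in which no feature
#' has positive importance is flagged unexplainable.
#'
#' @param fit A `metdep_forest` fitted with `importance = TRUE`.
#' @param features The feature table or matrix used to fit it.
#' @param y The response used to fit it.
#' @param categories Optional named character vector feature -> category.
#' @return List with `fit` (the refit forest, or `NULL`), `kept` (features
#'   retained), `importances` (data.frame sorted by decreasing scaled
#'   importance, with `category` when supplied), `top_feature`, `top5`,
#'   `unexplainable` (logical), and `oob` (goodness of fit of the refit).
#' @export
importance_and_refit <- function(fit, features, y, categories = NULL) {
  stopifnot(inherits(fit, "metdep_forest"), !is.null(fit$importance))
  X <- if (is.list(features) && !is.null(features$matrix)) features$matrix else features
  if (is.null(categories) && is.list(features) && !is.null(features$categories)) {
    categories <- features$categories
  }
  keep <- fit$importance$feature[fit$importance$raw > 0]
  if (length(keep) == 0L) {
    return(list(fit = NULL, kept = character(0),
                importances = fit$importance[0, ], top_feature = NA_character_,
                top5 = character(0), unexplainable = TRUE,
                oob = list(r = NA_real_, p = NA_real_, ok = FALSE)))
  }
  refit <- fit_forest(X[, keep, drop = FALSE], y, n_trees = fit$n_trees,
                      min_leaf = fit$min_leaf, seed = fit$seed,
                      importance = TRUE)
  imp <- refit$importance
  imp <- imp[order(-imp$scaled, imp$feature), , drop = FALSE]
  rownames(imp) <- NULL
  if (!is.null(categories)) imp$category <- unname(categories[imp$feature])
  list(fit = refit, kept = keep, importances = imp,
       top_feature = imp$feature[1],
       top5 = utils::head(imp$feature, 5L), unexplainable = FALSE,
       oob = oob_goodness_of_fit(refit, y))
}
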