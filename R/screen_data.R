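# Screen dataset container: dependency / expression / CNV / mutation
# matrices aligned to a shared, ordered cell-line axis plus annotations.

#' Construct an aligned screen dataset
#'
#' All four matrices are reduced to the ordered intersection of their
#' cell-line axes with the annotation table; annotations missing any of
#' medium, culture type or lineage get an explicit `"unknown"` level.
#' Dependency scores follow the screen convention: lower = more essential.
#'
#' @param dependency,expression,cnv Numeric gene x cell-line matrices with
#'   dimnames (`NA` allowed).
#' @param mutations Binary oncogene x cell-line matrix.
#' @param annotations data.frame with columns `cell_line`, `medium`,
#'   `culture_type`, `lineage`.
#' @param metabolic_genes Character vector of gene ids designated metabolic
#'   (typically the metabolic model's genes intersected with the dependency
#'   rows).
#' @return Object of class `screen_dataset`.
#' @export
screen_dataset <- function(dependency, expression, cnv, mutations,
                           annotations, metabolic_genes = character(0)) {
  for (nm in c("dependency", "expression", "cnv", "mutations")) {
    m <- get(nm)
    if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m))) {
      stop(nm, " must be a matrix with row and column names")
    }
    if (anyDuplicated(rownames(m))) {
      stop("duplicate gene rows in ", nm, ": ",
           paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
    }
  }
  stopifnot(is.data.frame(annotations), "cell_line" %in% names(annotations))
  if (anyDuplicated(annotations$cell_line)) stop("duplicate cell-line annotations")
  for (col in c("medium", "culture_type", "lineage")) {
    if (!col %in% names(annotations)) annotations[[col]] <- "unknown"
    v <- as.character(annotations[[col]])
    v[is.na(v) | !nzchar(v)] <- "unknown"
    annotations[[col]] <- v
  }
  axes <- list(colnames(dependency), colnames(expression), colnames(cnv),
               colnames(mutations), annotations$cell_line)
  common <- Reduce(intersect, axes)
  if (length(common) == 0L) stop("empty intersection of cell-line axes")
  dropped <- setdiff(unique(unlist(axes)), common)
  if (length(dropped)) {
    message(sprintf("dropping %d cell line(s) absent from some input: %s",
                    length(dropped), paste(utils::head(dropped, 10), collapse = ", ")))
  }
  annotations <- annotations[match(common, annotations$cell_line), , drop = FALSE]
  rownames(annotations) <- NULL
  structure(list(
    dependency = dependency[, common, drop = FALSE],
    expression = expression[, common, drop = FALSE],
    cnv = cnv[, common, drop = FALSE],
    mutations = mutations[, common, drop = FALSE],
    annotations = annotations,
    metabolic_genes = intersect(metabolic_genes, rownames(dependency)),
    cell_lines = common
  ), class = "screen_dataset")
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat(sprintf(paste0("<screen_dataset> %d cell lines; dependency %d genes ",
                     "(%d metabolic), expression %d, cnv %d, mutations %d oncogenes\n"),
              length(x$cell_lines), nrow(x$dependency), length(x$metabolic_genes),
              nrow(x$expression), nrow(x$cnv), nrow(x$mutations)))
  invisible(x)
}

read_gene_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  gene_col <- names(dt)[1]
  genes <- as.character(dt[[gene_col]])
  rest <- dt[, -1, with = FALSE]
  for (j in names(rest)) {
    v <- rest[[j]]
    if (!is.numeric(v) && !is.logical(v)) {
      bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric value in %s at row %s, column %s",
                   basename(path), genes[bad], j))
    }
  }
  m <- as.matrix(rest)
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Load a screen dataset from delimited text files
#'
#' Each matrix file is a TSV/CSV (auto-detected by `data.table::fread`)
#' whose first column holds gene (or oncogene) ids and remaining columns
#' cell lines. The annotation file needs columns `cell_line`, `medium`,
#' `culture_type`, `lineage`. Cell-line axes are intersected and ordered
#' identically; lines missing from any input are dropped with a message.
#'
#' @param dependency_path,expression_path,cnv_path,mutation_path,annotation_path
#'   File paths.
#' @param metabolic_genes Character vector of metabolic gene ids.
#' @param media_map Optional named character vector normalizing free-text
#'   media labels to a controlled vocabulary; unmapped labels become
#'   `"other"`. `NULL` keeps labels as-is.
#' @return A [screen_dataset()].
#' @export
load_screen <- function(dependency_path, expression_path, cnv_path,
                        mutation_path, annotation_path,
                        metabolic_genes = character(0), media_map = NULL) {
  ann <- as.data.frame(data.table::fread(annotation_path, header = TRUE,
                                         colClasses = "character"))
  if (!is.null(media_map)) {
    mapped <- unname(media_map[ann$medium])
    mapped[is.na(mapped)] <- "other"
    ann$medium <- mapped
  }
  screen_dataset(
    dependency = read_gene_matrix(dependency_path),
    expression = read_gene_matrix(expression_path),
    cnv = read_gene_matrix(cnv_path),
    mutations = read_gene_matrix(mutation_path),
    annotations = ann,
    metabolic_genes = metabolic_genes
  )
}

#' Filter genes by dependency-score variability
#'
#' A gene passes when its dependency score in at least one cell line lies
#' more than `k` standard deviations below the gene's mean — the screens'
#' signature of a strong cell line-specific essentiality. Statistics use
#' non-missing entries and the sample (n-1) standard deviation; genes with
#' fewer than 3 non-missing values or zero variance fail. The three
#' pipeline stages use k = 6 (media analysis), 4 (pairwise correlations)
#' and 2 (predictive models).
#'
#' @param dependency Numeric gene x cell-line matrix.
#' @param k Positive number of standard deviations.
#' @param details If `TRUE`, return a per-gene data.frame instead of the
#'   passing gene names.
#' @return Character vector of passing genes, or a data.frame with columns
#'   `gene`, `passes`, `min_score`, `mean`, `sd`, `threshold_k`.
#' @export
variability_filter <- function(dependency, k, details = FALSE) {
  stopifnot(is.matrix(dependency), k > 0)
  n_ok <- rowSums(!is.na(dependency))
  mu <- rowMeans(dependency, na.rm = TRUE)
  sd_ <- apply(dependency, 1L, stats::sd, na.rm = TRUE)
  min_ <- suppressWarnings(apply(dependency, 1L, min, na.rm = TRUE))
  passes <- n_ok >= 3L & !is.na(sd_) & sd_ > 0 & min_ < mu - k * sd_
  if (details) {
    return(data.frame(gene = rownames(dependency), passes = unname(passes),
                      min_score = unname(min_), mean = unname(mu),
                      sd = unname(sd_), threshold_k = k,
                      stringsAsFactors = FALSE))
  }
  rownames(dependency)[passes]
}
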