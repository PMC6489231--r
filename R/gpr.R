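# Gene-protein-reaction (GPR) boolean rules.
#
# A parsed rule is either NULL (no gene association), a character scalar of
# class "gpr_leaf" (a gene), or a list of class "gpr_and"/"gpr_or" whose
# elements are themselves parsed rules. AND binds tighter than OR; n-ary
# nodes are flattened.

#' Parse a gene-protein-reaction rule string
#'
#' Parses boolean gene-association rules of the kind attached to reactions in
#' genome-scale metabolic models, e.g. `"(g1 and g2) or g3"`. `AND`/`OR` are
#' case-insensitive; `AND` binds tighter than `OR`; parentheses override
#' precedence. Nested nodes with the same operator are flattened to n-ary
#' nodes, so `"a or b or c"` parses to a single OR over three leaves.
#'
#' @param rule Character scalar. The empty string (or `NA`) yields `NULL`,
#'   meaning "no gene association".
#' @return `NULL`, a leaf (class `gpr_leaf`), or an n-ary node of class
#'   `gpr_and` or `gpr_or`.
#' @export
#' @examples
#' parse_gpr("g1 and (g2 or g3)")
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0L) return(NULL)
  stopifnot(is.character(rule), length(rule) == 1L)
  if (is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  node <- gpr_parse_or(st, rule)
  if (st$pos <= length(st$toks)) {
    gpr_err(rule, st$toks[[st$pos]], "unexpected token")
  }
  node
}

gpr_tokenize <- function(rule) {
  # token: list(type, text, at) with `at` the 1-based character position
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, rule, perl = TRUE)[[1]]
  if (m[1] == -1L) return(list())
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  lapply(seq_along(starts), function(i) {
    txt <- substr(rule, starts[i], starts[i] + lens[i] - 1L)
    type <- if (txt == "(") "lpar" else if (txt == ")") "rpar"
      else if (tolower(txt) %in% c("and", "&", "&&")) "and"
      else if (tolower(txt) %in% c("or", "|", "||")) "or"
      else "gene"
    list(type = type, text = txt, at = starts[i])
  })
}

gpr_err <- function(rule, tok, msg) {
  at <- if (is.null(tok)) nchar(rule) + 1L else tok$at
  stop(sprintf("GPR parse error at position %d in %s: %s", at,
               deparse(rule), msg), call. = FALSE)
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NULL

gpr_parse_or <- function(st, rule) {
  parts <- list(gpr_parse_and(st, rule))
  while (!is.null(tok <- gpr_peek(st)) && tok$type == "or") {
    st$pos <- st$pos + 1L
    parts <- c(parts, list(gpr_parse_and(st, rule)))
  }
  gpr_node("gpr_or", parts)
}

gpr_parse_and <- function(st, rule) {
  parts <- list(gpr_parse_atom(st, rule))
  while (!is.null(tok <- gpr_peek(st)) && tok$type == "and") {
    st$pos <- st$pos + 1L
    parts <- c(parts, list(gpr_parse_atom(st, rule)))
  }
  gpr_node("gpr_and", parts)
}

gpr_parse_atom <- function(st, rule) {
  tok <- gpr_peek(st)
  if (is.null(tok)) gpr_err(rule, NULL, "dangling operator: expected gene or '('")
  if (tok$type == "gene") {
    st$pos <- st$pos + 1L
    return(structure(tok$text, class = "gpr_leaf"))
  }
  if (tok$type == "lpar") {
    st$pos <- st$pos + 1L
    node <- gpr_parse_or(st, rule)
    close <- gpr_peek(st)
    if (is.null(close) || close$type != "rpar") {
      gpr_err(rule, close, "unbalanced parentheses: expected ')'")
    }
    st$pos <- st$pos + 1L
    return(node)
  }
  gpr_err(rule, tok, sprintf("expected gene or '(', got '%s'", tok$text))
}

gpr_node <- function(cls, parts) {
  if (length(parts) == 1L) return(parts[[1]])
  # flatten same-operator children
  flat <- list()
  for (p in parts) {
    if (inherits(p, cls)) flat <- c(flat, unclass(p)) else flat <- c(flat, list(p))
  }
  structure(flat, class = cls)
}

#' Genes appearing in a parsed GPR tree
#' @param gpr A parsed rule as returned by [parse_gpr()].
#' @return Character vector of unique gene ids (empty for `NULL`).
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character(0))
  if (inherits(gpr, "gpr_leaf")) return(as.character(gpr))
  unique(unlist(lapply(unclass(gpr), gpr_genes), use.names = FALSE))
}

#' Render a parsed GPR tree back to a rule string
#' @param gpr A parsed rule.
#' @return Character scalar ("" for `NULL`).
#' @export
gpr_to_string <- function(gpr) {
  if (is.null(gpr)) return("")
  if (inherits(gpr, "gpr_leaf")) return(as.character(gpr))
  op <- if (inherits(gpr, "gpr_and")) " and " else " or "
  parts <- vapply(unclass(gpr), function(p) {
    s <- gpr_to_string(p)
    if (!inherits(p, "gpr_leaf")) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = op)
}

# Pairs of genes that are OR-alternatives somewhere in the tree.
# Two leaves are alternatives iff their lowest common ancestor is an OR node.
gpr_or_pairs <- function(gpr) {
  if (is.null(gpr) || inherits(gpr, "gpr_leaf")) {
    return(matrix(character(0), ncol = 2))
  }
  kids <- unclass(gpr)
  sub <- lapply(kids, gpr_or_pairs)
  own <- matrix(character(0), ncol = 2)
  if (inherits(gpr, "gpr_or")) {
    sets <- lapply(kids, gpr_genes)
    for (i in seq_along(sets)) {
      for (j in seq_along(sets)) {
        if (i < j) {
          own <- rbind(own, as.matrix(expand.grid(sets[[i]], sets[[j]],
                                                  stringsAsFactors = FALSE)))
        }
      }
    }
  }
  do.call(rbind, c(list(own), sub))
}
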