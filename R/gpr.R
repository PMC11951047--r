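# Gene-protein-reaction (GPR) boolean expressions.
#
# A GPR is a boolean formula over gene ids with `and` (complex) and `or`
# (isozymes). We parse to a nested list AST, evaluate under knockouts, and
# expand to disjunctive normal form (DNF) — the form GECKO-style enzyme
# integration needs: each OR branch is an alternative catalyst, each AND
# conjunction an enzyme complex.

gpr_tokenize <- function(x) {
  x <- gsub("&&|&", " and ", x)
  x <- gsub("\\|\\||\\|", " or ", x)
  x <- gsub("([()])", " \\1 ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a GPR string into an abstract syntax tree
#'
#' @param x GPR string, e.g. `"(g1 and g2) or g3"`. `and`/`or` are
#'   case-insensitive; `&`/`|` are accepted. Empty or `NA` strings give `NULL`
#'   (no gene association).
#' @return `NULL`, a gene id (character scalar), or a list
#'   `list(op = "and"|"or", args = list(...))`.
#' @export
parse_gpr <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(trimws(x))) return(NULL)
  toks <- gpr_tokenize(x)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() {
    t <- peek()
    pos <<- pos + 1L
    t
  }
  parse_or <- function() {
    left <- parse_and()
    args <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      args <- c(args, list(parse_and()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    left <- parse_atom()
    args <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      args <- c(args, list(parse_atom()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_atom <- function() {
    t <- take()
    if (is.na(t)) abort("GPR parse error: unexpected end of expression")
    if (t == "(") {
      inner <- parse_or()
      if (!identical(take(), ")")) abort("GPR parse error: unbalanced parentheses")
      return(inner)
    }
    if (t %in% c(")", "and", "or", "AND", "OR")) {
      abort(paste0("GPR parse error: unexpected token '", t, "'"))
    }
    t
  }
  ast <- parse_or()
  if (pos <= length(toks)) {
    abort(paste0("GPR parse error: trailing tokens near '", toks[pos], "'"))
  }
  ast
}

#' Evaluate a GPR under a set of knocked-out genes
#'
#' @param x GPR string or AST from [parse_gpr()].
#' @param knocked character vector of gene ids set to FALSE; all other genes
#'   are TRUE.
#' @return logical scalar; reactions with no gene association return `TRUE`
#'   (they are not gene-controlled).
#' @export
eval_gpr <- function(x, knocked = character()) {
  ast <- if (is.character(x) && length(x) == 1L && !is.list(x)) parse_gpr(x) else x
  if (is.null(ast)) return(TRUE)
  ev <- function(node) {
    if (is.character(node)) return(!(node %in% knocked))
    vals <- vapply(node$args, ev, logical(1))
    if (node$op == "and") all(vals) else any(vals)
  }
  ev(ast)
}

#' Genes mentioned in a GPR
#' @param x GPR string or AST.
#' @return character vector of gene ids (unique, in order of appearance).
#' @export
gpr_genes <- function(x) {
  ast <- if (is.character(x) && !is.list(x)) parse_gpr(x) else x
  if (is.null(ast)) return(character())
  walk <- function(node) {
    if (is.character(node)) return(node)
    unlist(lapply(node$args, walk))
  }
  unique(walk(ast))
}

#' Expand a GPR to disjunctive normal form
#'
#' @param x GPR string or AST.
#' @param max_terms guard against exponential blow-up (default 512 branches).
#' @return list of character vectors; each vector is one OR branch, i.e. the
#'   set of genes whose products form the catalysing complex. `list()` for a
#'   gene-free GPR.
#' @export
gpr_dnf <- function(x, max_terms = 512L) {
  ast <- if (is.character(x) && !is.list(x)) parse_gpr(x) else x
  if (is.null(ast)) return(list())
  expand <- function(node) {
    if (is.character(node)) return(list(node))
    branches <- lapply(node$args, expand)
    if (node$op == "or") {
      out <- do.call(c, branches)
    } else {
      # cartesian product of AND over branch lists
      out <- Reduce(function(acc, b) {
        res <- list()
        for (a in acc) for (term in b) res <- c(res, list(union(a, term)))
        if (length(res) > max_terms) abort("GPR DNF expansion exceeds max_terms")
        res
      }, branches, accumulate = FALSE)
    }
    if (length(out) > max_terms) abort("GPR DNF expansion exceeds max_terms")
    out
  }
  terms <- expand(ast)
  terms <- lapply(terms, function(g) sort(unique(g)))
  unique(terms)
}
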