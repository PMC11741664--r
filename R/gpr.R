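#' Gene-protein-reaction (GPR) boolean expressions
#'
#' A GPR rule links genes to the availability of a reaction: `and` encodes an
#' enzyme complex (every subunit required), `or` encodes isozymes (any one
#' suffices). Internally a rule is a tree of nodes, each either
#' `list(gene = "<id>")` or `list(op = "and"|"or", args = list(...))`.
#' The empty rule (`NULL`) marks an orphan reaction.
#'
#' @name gpr
NULL

#' Parse a GPR rule string
#'
#' Accepts `and`/`or` (case-insensitive, also `&`/`|`) with parentheses.
#' `or` binds looser than `and`, mirroring the usual convention of
#' constraint-based model files.
#'
#' @param text rule string such as `"(gA and gB) or gC"`; `""`, `NA` and
#'   `NULL` give the empty rule.
#' @return a `gemflux_gpr` tree, or `NULL` for the empty rule.
#' @examples
#' gpr_parse("(gA and gB) or gC")
#' @export
gpr_parse <- function(text) {
  if (is.null(text) || length(text) == 0 || is.na(text[1]) || !nzchar(trimws(text[1]))) {
    return(NULL)
  }
  text <- gsub("&&|&", " and ", text)
  text <- gsub("\\|\\||\\|", " or ", text)
  toks <- regmatches(text, gregexpr("\\(|\\)|[^\\s()]+", text, perl = TRUE))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_or <- function() {
    node <- parse_and()
    args <- list(node)
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    node <- parse_atom()
    args <- list(node)
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      args[[length(args) + 1L]] <- parse_atom()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_atom <- function() {
    t <- take()
    if (is.na(t)) stop("unexpected end of GPR rule: '", text, "'")
    if (t == "(") {
      node <- parse_or()
      if (is.na(peek()) || take() != ")") stop("unbalanced parentheses in GPR: '", text, "'")
      return(node)
    }
    if (t == ")" || tolower(t) %in% c("and", "or")) {
      stop("unexpected token '", t, "' in GPR: '", text, "'")
    }
    list(gene = t)
  }
  tree <- parse_or()
  if (pos <= length(toks)) stop("trailing tokens in GPR: '", text, "'")
  structure(tree, class = "gemflux_gpr")
}

#' Render a GPR tree as a rule string
#' @param gpr a GPR tree or `NULL`.
#' @return character scalar (`""` for the empty rule).
#' @export
gpr_deparse <- function(gpr) {
  if (is.null(gpr)) return("")
  rec <- function(node, parent_op = NULL) {
    if (!is.null(node$gene)) return(node$gene)
    inner <- vapply(node$args, rec, character(1), parent_op = node$op)
    joined <- paste(inner, collapse = paste0(" ", node$op, " "))
    if (!is.null(parent_op) && !identical(parent_op, node$op)) paste0("(", joined, ")") else joined
  }
  rec(unclass(gpr))
}

#' Genes appearing in a GPR tree
#' @param gpr a GPR tree or `NULL`.
#' @return character vector of unique gene ids (empty for the empty rule).
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character(0))
  out <- character(0)
  rec <- function(node) {
    if (!is.null(node$gene)) out <<- c(out, node$gene)
    else lapply(node$args, rec)
  }
  rec(gpr)
  unique(out)
}

#' Evaluate a GPR tree under gene deletions
#'
#' @param gpr a GPR tree or `NULL`.
#' @param deleted character vector of deleted gene ids.
#' @return `TRUE` when the reaction remains catalysable. The empty rule
#'   evaluates to `TRUE`: an orphan reaction is unaffected by gene deletions.
#' @export
gpr_eval <- function(gpr, deleted = character(0)) {
  if (is.null(gpr)) return(TRUE)
  rec <- function(node) {
    if (!is.null(node$gene)) return(!(node$gene %in% deleted))
    vals <- vapply(node$args, rec, logical(1))
    if (node$op == "and") all(vals) else any(vals)
  }
  rec(gpr)
}

#' Substitute gene ids in a GPR tree
#'
#' Leaves named in `map` are replaced by their mapped value; other leaves are
#' kept untouched.
#'
#' @param gpr a GPR tree or `NULL`.
#' @param map named character vector, `old id -> new id`.
#' @return the rewritten tree.
#' @export
gpr_substitute <- function(gpr, map) {
  if (is.null(gpr)) return(NULL)
  rec <- function(node) {
    if (!is.null(node$gene)) {
      if (node$gene %in% names(map)) node$gene <- unname(map[[node$gene]])
      return(node)
    }
    node$args <- lapply(node$args, rec)
    node
  }
  structure(rec(unclass(gpr)), class = "gemflux_gpr")
}

#' Prune genes from a GPR tree
#'
#' Removes the given leaves. An `or` branch survives as long as one argument
#' survives; an `and` branch dies when any argument dies. Used when stripping
#' template-model genes from a merged draft: isozyme alternatives are dropped
#' silently while broken complexes orphan the reaction.
#'
#' @param gpr a GPR tree or `NULL`.
#' @param genes character vector of gene ids to remove.
#' @return the pruned tree, or `NULL` when nothing survives.
#' @export
gpr_prune <- function(gpr, genes) {
  if (is.null(gpr)) return(NULL)
  rec <- function(node) {
    if (!is.null(node$gene)) {
      if (node$gene %in% genes) return(NULL)
      return(node)
    }
    kept <- Filter(Negate(is.null), lapply(node$args, rec))
    if (node$op == "and" && length(kept) < length(node$args)) return(NULL)
    if (length(kept) == 0) return(NULL)
    if (length(kept) == 1) return(kept[[1]])
    list(op = node$op, args = kept)
  }
  out <- rec(unclass(gpr))
  if (is.null(out)) NULL else structure(out, class = "gemflux_gpr")
}

#' Combine two GPR trees with `or`
#'
#' Used when collapsing duplicate reactions: the merged reaction is available
#' if either original gene set is.
#'
#' @param a,b GPR trees or `NULL`.
#' @return combined tree.
#' @export
gpr_or <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (identical(gpr_deparse(a), gpr_deparse(b))) return(a)
  structure(list(op = "or", args = list(unclass(a), unclass(b))), class = "gemflux_gpr")
}
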