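# Gene-protein-reaction (GPR) rules: boolean AND/OR expressions over gene
# ids, e.g. "g1 and (g2 or g3)". Parsed once into a nested list and
# evaluated against a named logical presence vector.

#' Parse a gene-protein-reaction rule
#'
#' Accepts the common textual GPR dialects: `and`/`or` (case-insensitive),
#' `&`/`|`, and parentheses. Gene ids are any other whitespace-delimited
#' tokens.
#'
#' @param rule GPR string; `""` or `NA` yield `NULL` (no rule).
#' @return a parse tree: a gene id (character scalar), or
#'   `list(op = "and"|"or", args = list(...))`; `NULL` for an empty rule.
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  spaced <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(spaced), "\\s+")[[1]]
  toks[tolower(toks) == "and" | toks == "&" | toks == "&&"] <- "and"
  toks[tolower(toks) == "or" | toks == "|" | toks == "||"] <- "or"

  pos <- 0L
  peek <- function() if (pos < length(toks)) toks[pos + 1L] else NA_character_
  take <- function() { pos <<- pos + 1L; toks[pos] }

  parse_factor <- function() {
    tk <- peek()
    if (is.na(tk)) abort_rgem("malformed GPR: unexpected end of rule", "rgem_gpr_error")
    if (tk == "(") {
      take()
      node <- parse_or()
      if (!identical(peek(), ")"))
        abort_rgem("malformed GPR: unbalanced parentheses", "rgem_gpr_error")
      take()
      return(node)
    }
    if (tk %in% c(")", "and", "or"))
      abort_rgem(sprintf("malformed GPR: unexpected token '%s'", tk), "rgem_gpr_error")
    take()
  }
  parse_and <- function() {
    args <- list(parse_factor())
    while (identical(peek(), "and")) { take(); args <- c(args, list(parse_factor())) }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (identical(peek(), "or")) { take(); args <- c(args, list(parse_and())) }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }

  tree <- parse_or()
  if (pos != length(toks))
    abort_rgem(sprintf("malformed GPR: trailing token '%s'", toks[pos + 1L]),
               "rgem_gpr_error")
  tree
}

#' Genes referenced by a GPR parse tree
#' @param tree result of [parse_gpr()].
#' @return character vector of gene ids (empty for `NULL`).
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character())
  if (is.character(tree)) return(tree)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

#' Evaluate a GPR tree against gene presence
#'
#' OR means any operand present; AND means all operands present. Genes
#' missing from `presence` are treated as absent.
#'
#' @param tree result of [parse_gpr()].
#' @param presence named logical vector (`TRUE` = present).
#' @return logical scalar; `NA` for a `NULL` tree (no rule).
#' @export
eval_gpr <- function(tree, presence) {
  if (is.null(tree)) return(NA)
  if (is.character(tree)) {
    val <- presence[tree]
    return(!is.na(val) && isTRUE(unname(val)))
  }
  vals <- vapply(tree$args, eval_gpr, logical(1), presence = presence)
  if (tree$op == "and") all(vals) else any(vals)
}
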