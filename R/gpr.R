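# Gene-protein-reaction (GPR) boolean expressions.
#
# A GPR is a finite tree whose leaves are gene identifiers and whose internal
# nodes are AND/OR operators with >= 2 children.  Represented as nested lists:
# leaves are `list(gene = "g1")`, nodes are `list(op = "and"|"or",
# args = list(...))`.

#' Parse a GPR string
#'
#' Parses boolean gene association strings such as `"(g1 or g2) and g3"`.
#' Operator keywords are case-insensitive (`and`/`AND`, `or`/`OR`); `and`
#' binds tighter than `or`; parentheses group.  Gene identifiers may contain
#' letters, digits, `.`, `_` and `-`.
#'
#' @param text GPR string. `NA` or `""` yields `NULL` (no gene association).
#' @return A GPR expression tree, or `NULL`.
#' @examples
#' parse_gpr("(g1 or g2) and g3")
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0L) return(NULL)
  if (length(text) != 1L) stop("`text` must be a single string")
  if (is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- .gpr_tokenize(text)
  state <- new.env(parent = emptyenv())
  state$toks <- toks
  state$pos <- 1L
  expr <- .gpr_parse_or(state)
  if (state$pos <= length(state$toks)) {
    stop(sprintf("GPR parse error in '%s': unexpected '%s'",
                 text, state$toks[state$pos]))
  }
  expr
}

.gpr_tokenize <- function(text) {
  m <- gregexpr("\\(|\\)|[A-Za-z0-9._-]+", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  rest <- gsub("\\(|\\)|[A-Za-z0-9._-]+|\\s+", "", text)
  if (nzchar(rest)) {
    stop(sprintf("GPR parse error in '%s': illegal characters '%s'", text, rest))
  }
  toks
}

.gpr_peek <- function(state) {
  if (state$pos > length(state$toks)) NA_character_ else state$toks[state$pos]
}

.gpr_parse_or <- function(state) {
  args <- list(.gpr_parse_and(state))
  while (!is.na(tok <- .gpr_peek(state)) && tolower(tok) == "or") {
    state$pos <- state$pos + 1L
    args <- c(args, list(.gpr_parse_and(state)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

.gpr_parse_and <- function(state) {
  args <- list(.gpr_parse_atom(state))
  while (!is.na(tok <- .gpr_peek(state)) && tolower(tok) == "and") {
    state$pos <- state$pos + 1L
    args <- c(args, list(.gpr_parse_atom(state)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

.gpr_parse_atom <- function(state) {
  tok <- .gpr_peek(state)
  if (is.na(tok)) stop("GPR parse error: unexpected end of expression")
  if (tok == "(") {
    state$pos <- state$pos + 1L
    expr <- .gpr_parse_or(state)
    if (!identical(.gpr_peek(state), ")")) {
      stop("GPR parse error: missing closing parenthesis")
    }
    state$pos <- state$pos + 1L
    return(expr)
  }
  if (tok == ")" || tolower(tok) %in% c("and", "or")) {
    stop(sprintf("GPR parse error: unexpected '%s'", tok))
  }
  state$pos <- state$pos + 1L
  list(gene = tok)
}

#' Deparse a GPR expression tree back to a string
#'
#' Inverse of [parse_gpr()] up to whitespace and redundant parentheses.
#'
#' @param expr GPR tree or `NULL`.
#' @return Character scalar (`""` for `NULL`).
#' @export
gpr_to_string <- function(expr) {
  if (is.null(expr)) return("")
  if (!is.null(expr$gene)) return(expr$gene)
  parts <- vapply(expr$args, function(a) {
    s <- gpr_to_string(a)
    if (is.null(a$gene)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", expr$op, " "))
}

#' Genes referenced by a GPR expression
#'
#' @param expr GPR tree or `NULL`.
#' @return Character vector of unique gene identifiers.
#' @export
gpr_genes <- function(expr) {
  if (is.null(expr)) return(character(0))
  if (!is.null(expr$gene)) return(expr$gene)
  unique(unlist(lapply(expr$args, gpr_genes)))
}
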