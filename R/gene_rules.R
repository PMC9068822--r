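#' Parse a gene-protein-reaction (GPR) rule string
#'
#' GPR rules are boolean expressions over gene identifiers, e.g.
#' `"(HK1 and GAPD) or PKM"`. `and`/`or` (any case), `&`/`|` and
#' parentheses are accepted. An empty or all-whitespace string denotes a
#' reaction with no gene association and parses to `NULL`.
#'
#' @param rule Character scalar with the rule, or `NULL`.
#' @return A parse tree: either `NULL`, a list `list(op = "gene", id = ...)`,
#'   or `list(op = "and"|"or", args = list(...))`.
#' @export
parse_gene_rule <- function(rule) {
  if (is.null(rule) || length(rule) == 0L) return(NULL)
  stopifnot(is.character(rule), length(rule) == 1L)
  s <- gsub("&&?", " and ", rule)
  s <- gsub("\\|\\|?", " or ", s)
  toks <- .gpr_tokenize(s)
  if (length(toks) == 0L) return(NULL)
  st <- list(pos = 1L, toks = toks)
  out <- .gpr_parse_or(st)
  if (out$state$pos <= length(toks)) {
    stop("trailing tokens in gene rule: ",
         paste(toks[out$state$pos:length(toks)], collapse = " "))
  }
  out$node
}

.gpr_tokenize <- function(s) {
  s <- gsub("([()])", " \\1 ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks[nzchar(toks)]
}

.gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NA_character_

.gpr_parse_or <- function(st) {
  left <- .gpr_parse_and(st)
  st <- left$state
  args <- list(left$node)
  while (!is.na(tk <- .gpr_peek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    nxt <- .gpr_parse_and(st)
    st <- nxt$state
    args <- c(args, list(nxt$node))
  }
  node <- if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  list(node = node, state = st)
}

.gpr_parse_and <- function(st) {
  left <- .gpr_parse_atom(st)
  st <- left$state
  args <- list(left$node)
  while (!is.na(tk <- .gpr_peek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    nxt <- .gpr_parse_atom(st)
    st <- nxt$state
    args <- c(args, list(nxt$node))
  }
  node <- if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  list(node = node, state = st)
}

.gpr_parse_atom <- function(st) {
  tk <- .gpr_peek(st)
  if (is.na(tk)) stop("unexpected end of gene rule")
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- .gpr_parse_or(st)
    st <- inner$state
    if (is.na(.gpr_peek(st)) || .gpr_peek(st) != ")")
      stop("unbalanced parenthesis in gene rule")
    st$pos <- st$pos + 1L
    return(list(node = inner$node, state = st))
  }
  if (tolower(tk) %in% c("and", "or", ")")) stop("unexpected token in gene rule: ", tk)
  st$pos <- st$pos + 1L
  list(node = list(op = "gene", id = tk), state = st)
}

#' List the gene identifiers appearing in a GPR parse tree
#'
#' @param tree Parse tree from [parse_gene_rule()] (or `NULL`).
#' @return Character vector of unique gene ids (empty for `NULL`).
#' @export
gene_rule_genes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (identical(tree$op, "gene")) return(tree$id)
  unique(unlist(lapply(tree$args, gene_rule_genes)))
}

#' Render a GPR parse tree back to a rule string
#'
#' @param tree Parse tree or `NULL`.
#' @return Character scalar ("" for `NULL`).
#' @export
deparse_gene_rule <- function(tree) {
  if (is.null(tree)) return("")
  if (identical(tree$op, "gene")) return(tree$id)
  parts <- vapply(tree$args, function(a) {
    s <- deparse_gene_rule(a)
    if (!identical(a$op, "gene")) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}
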