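## Gene-protein-reaction (GPR) rules: parsing and numeric evaluation.
##
## A GPR is a boolean expression over gene identifiers, e.g.
## "(g1 and g2) or g3".  AND encodes an enzyme complex (limited by its
## scarcest subunit), OR encodes isozymes (abundances add).  Evaluating a
## rule against a gene-abundance vector therefore uses min for AND and
## sum for OR -- the standard convention for mapping expression onto
## enzyme capacity.

#' Parse a gene-protein-reaction rule
#'
#' Parses a boolean GPR expression ("and"/"or"/parentheses, case
#' insensitive) into an expression tree. Gene identifiers may contain
#' alphanumerics, `_`, `.`, `-`, `(`...`)` is grouping only.
#'
#' @param gpr character scalar; `""`/`NA` yield `NULL` (no rule).
#' @return a tree: either a gene id (character scalar) or
#'   `list(op = "and"|"or", args = list(...))`; `NULL` for an empty rule.
#' @examples
#' parse_gpr("(gA and gB) or gC")
#' @export
parse_gpr <- function(gpr) {
  if (is.null(gpr) || length(gpr) == 0 || is.na(gpr)) return(NULL)
  stopifnot(is.character(gpr), length(gpr) == 1)
  if (!nzchar(trimws(gpr))) return(NULL)
  toks <- gpr_tokenize(gpr)
  st <- list(toks = toks, pos = 1L)
  res <- gpr_parse_or(st)
  if (res$state$pos <= length(toks)) {
    stop(sprintf("GPR parse error at token %d ('%s') in rule '%s'",
                 res$state$pos, toks[res$state$pos], gpr), call. = FALSE)
  }
  res$node
}

gpr_tokenize <- function(x) {
  m <- gregexpr("\\(|\\)|[A-Za-z0-9_.:-]+", x, perl = TRUE)[[1]]
  if (m[1] == -1) stop(sprintf("GPR parse error: no tokens in '%s'", x), call. = FALSE)
  toks <- regmatches(x, list(m))[[1]]
  # anything not matched must be whitespace
  residue <- gsub("\\(|\\)|[A-Za-z0-9_.:-]+|\\s+", "", x, perl = TRUE)
  if (nzchar(residue)) {
    stop(sprintf("GPR parse error: unexpected character '%s' in rule '%s'",
                 substr(residue, 1, 1), x), call. = FALSE)
  }
  toks
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_parse_or <- function(st) {
  lhs <- gpr_parse_and(st)
  st <- lhs$state
  args <- list(lhs$node)
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "or") {
    st$pos <- st$pos + 1L
    rhs <- gpr_parse_and(st)
    st <- rhs$state
    args <- c(args, list(rhs$node))
  }
  node <- if (length(args) == 1) args[[1]] else list(op = "or", args = args)
  list(node = node, state = st)
}

gpr_parse_and <- function(st) {
  lhs <- gpr_parse_atom(st)
  st <- lhs$state
  args <- list(lhs$node)
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "and") {
    st$pos <- st$pos + 1L
    rhs <- gpr_parse_atom(st)
    st <- rhs$state
    args <- c(args, list(rhs$node))
  }
  node <- if (length(args) == 1) args[[1]] else list(op = "and", args = args)
  list(node = node, state = st)
}

gpr_parse_atom <- function(st) {
  tok <- gpr_peek(st)
  if (is.na(tok)) stop(sprintf("GPR parse error: unexpected end of rule at token %d", st$pos),
                       call. = FALSE)
  if (tok == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    st <- inner$state
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")") {
      stop(sprintf("GPR parse error: missing ')' at token %d", st$pos), call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(list(node = inner$node, state = st))
  }
  if (tok == ")" || tolower(tok) %in% c("and", "or")) {
    stop(sprintf("GPR parse error: unexpected '%s' at token %d", tok, st$pos), call. = FALSE)
  }
  st$pos <- st$pos + 1L
  list(node = tok, state = st)
}

#' Genes referenced by a GPR rule
#' @param gpr rule string or parsed tree.
#' @return character vector of gene ids (empty for no rule).
#' @export
gpr_genes <- function(gpr) {
  node <- if (is.character(gpr) && is.null(attr(gpr, "parsed"))) parse_gpr(gpr) else gpr
  if (is.null(node)) return(character())
  if (is.character(node)) return(node)
  unique(unlist(lapply(node$args, gpr_genes)))
}

#' Evaluate a GPR rule against gene abundances
#'
#' Maps gene-level abundance onto enzyme capacity: AND nodes take the
#' minimum of their children (complex limited by scarcest subunit), OR
#' nodes the sum (isozymes pool). An empty rule is "unconstrained" and
#' returns `Inf`.
#'
#' Genes missing from `abundance` are imputed per `missing`:
#' `"median"` (default) substitutes the median of the supplied
#' abundances -- zero would spuriously shut reactions on identifier
#' mapping gaps; `"zero"` substitutes 0; `"skip"` treats the whole rule
#' as absent (returns `Inf`).
#'
#' @param gpr rule string or tree from [parse_gpr()].
#' @param abundance named non-negative numeric vector, gene id -> abundance.
#' @param missing one of `"median"`, `"zero"`, `"skip"`.
#' @return non-negative numeric scalar; `Inf` means unconstrained.
#' @examples
#' evaluate_gpr("(gA and gB)", c(gA = 2, gB = 3))      # 2
#' evaluate_gpr("(gA or gB)", c(gA = 2, gB = 3))       # 5
#' @export
evaluate_gpr <- function(gpr, abundance, missing = c("median", "zero", "skip")) {
  missing <- match.arg(missing)
  node <- if (is.character(gpr) && length(gpr) == 1 && is.null(attr(gpr, "parsed")))
    parse_gpr(gpr) else gpr
  if (is.null(node)) return(Inf)
  stopifnot(is.numeric(abundance))
  if (any(abundance < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  need <- setdiff(gpr_genes(node), names(abundance))
  if (length(need)) {
    if (missing == "skip") return(Inf)
    fill <- if (missing == "median") {
      if (length(abundance) == 0) 0 else stats::median(abundance)
    } else 0
    abundance <- c(abundance, stats::setNames(rep(fill, length(need)), need))
  }
  gpr_eval_node(node, abundance)
}

gpr_eval_node <- function(node, abundance) {
  if (is.character(node)) return(unname(abundance[[node]]))
  vals <- vapply(node$args, gpr_eval_node, numeric(1), abundance = abundance)
  if (node$op == "and") min(vals) else sum(vals)
}

#' Render a GPR tree back to its string form
#' @param node tree from [parse_gpr()] (or `NULL`).
#' @return character scalar (`""` for no rule).
#' @export
deparse_gpr <- function(node) {
  if (is.null(node)) return("")
  if (is.character(node)) return(node)
  parts <- vapply(node$args, function(a) {
    s <- deparse_gpr(a)
    if (!is.character(a)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", node$op, " "))
}
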