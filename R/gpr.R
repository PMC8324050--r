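# Gene-protein-reaction (GPR) boolean rules.
#
# Rules are stored as strings in the community "gene_reaction_rule" dialect:
# gene ids combined with 'and' / 'or' (case-insensitive) and parentheses.
# The empty string means "no gene association" and always evaluates TRUE.

.gpr_tokenize <- function(x) {
  pat <- "\\(|\\)|[A-Za-z0-9_.:-]+"
  m <- gregexpr(pat, x)[[1]]
  if (m[1] == -1) return(character())
  regmatches(x, list(m))[[1]]
}

#' Parse a GPR rule into a boolean expression tree
#'
#' @param x a rule string, e.g. \code{"(gA and gB) or gC"}. Operators
#'   \code{and}/\code{or} (any case, also \code{&}/\code{|}) with
#'   parentheses; everything else is a gene id leaf.
#' @return A tree: a gene id (character leaf), or a list with elements
#'   \code{op} (\code{"and"}/\code{"or"}) and \code{args} (list of subtrees).
#'   The empty rule parses to \code{NULL}.
#' @examples
#' parseGpr("(gA and gB) or gC")
#' @export
parseGpr <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(trimws(x))) return(NULL)
  toks <- .gpr_tokenize(x)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L }
  is_op <- function(t, op) !is.na(t) && tolower(t) %in% op

  parse_or <- function() {
    args <- list(parse_and())
    while (is_op(peek(), c("or", "|", "||"))) {
      advance()
      args <- c(args, list(parse_and()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (is_op(peek(), c("and", "&", "&&"))) {
      advance()
      args <- c(args, list(parse_atom()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) stop("malformed GPR rule: '", x, "'", call. = FALSE)
    if (t == "(") {
      advance()
      node <- parse_or()
      if (!identical(peek(), ")"))
        stop("unbalanced parentheses in GPR rule: '", x, "'", call. = FALSE)
      advance()
      return(node)
    }
    if (t == ")" || is_op(t, c("and", "or", "&", "|")))
      stop("malformed GPR rule: '", x, "'", call. = FALSE)
    advance()
    t
  }
  out <- parse_or()
  if (pos <= length(toks))
    stop("trailing tokens in GPR rule: '", x, "'", call. = FALSE)
  out
}

#' Evaluate a GPR rule under a set of gene deletions
#'
#' AND nodes require all children, OR nodes any child; a leaf is TRUE iff
#' its gene is not deleted. The empty rule is TRUE (no gene association
#' means the reaction cannot be knocked out genetically).
#'
#' @param gpr a rule string or a tree from [parseGpr()].
#' @param deleted character vector of deleted gene ids.
#' @return logical: can the reaction still be catalyzed?
#' @examples
#' evaluateGpr("gA and gB", deleted = "gA")   # FALSE
#' evaluateGpr("gA or gB",  deleted = "gA")   # TRUE
#' @export
evaluateGpr <- function(gpr, deleted = character()) {
  if (is.character(gpr) && length(gpr) == 1L) gpr <- parseGpr(gpr)
  rec <- function(node) {
    if (is.null(node)) return(TRUE)
    if (is.character(node)) return(!(node %in% deleted))
    vals <- vapply(node$args, rec, logical(1))
    if (node$op == "and") all(vals) else any(vals)
  }
  rec(gpr)
}

#' List the gene ids referenced by a GPR rule
#'
#' @param gpr a rule string or parsed tree.
#' @return character vector of unique gene ids (empty for the empty rule).
#' @export
gprGenes <- function(gpr) {
  if (is.character(gpr) && length(gpr) == 1L) gpr <- parseGpr(gpr)
  rec <- function(node) {
    if (is.null(node)) return(character())
    if (is.character(node)) return(node)
    unlist(lapply(node$args, rec))
  }
  unique(rec(gpr))
}

#' Render a parsed GPR tree back to a rule string
#'
#' @param gpr parsed tree (or string, returned as-is after normalization).
#' @return canonical rule string, \code{""} for the empty rule.
#' @export
deparseGpr <- function(gpr) {
  if (is.character(gpr) && length(gpr) == 1L) gpr <- parseGpr(gpr)
  rec <- function(node, parent_op = "") {
    if (is.null(node)) return("")
    if (is.character(node)) return(node)
    sep <- paste0(" ", node$op, " ")
    s <- paste(vapply(node$args, rec, character(1), parent_op = node$op),
               collapse = sep)
    if (nzchar(parent_op) && parent_op != node$op) paste0("(", s, ")") else s
  }
  rec(gpr)
}
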