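#' Gene-protein-reaction (GPR) rules
#'
#' A GPR rule is a boolean expression over gene identifiers stating which
#' gene products enable a reaction ("g1 and g2" = enzyme complex,
#' "g1 or g2" = isozymes). `parse_gpr()` turns the textual rule into an
#' expression tree, `evaluate_gpr()` evaluates it against a set of present
#' genes, `gpr_genes()` lists the genes it mentions and `render_gpr()`
#' serializes the tree back to text.
#'
#' The grammar accepts `and`/`or` in any case as well as `&&`/`||` and
#' `&`/`|`; `and` binds tighter than `or`; parentheses override. Nested
#' nodes with the same connective are flattened, so rendering followed by
#' re-parsing reproduces the tree exactly.
#'
#' @param text GPR rule as a single string. Empty or all-whitespace text
#'   yields `NULL` (no rule), which callers must handle explicitly.
#' @return `parse_gpr()`: an object of class `gpr` (a leaf is a gene id
#'   string; an inner node is `list(op = "and"|"or", args = list(...))`),
#'   or `NULL` for empty input.
#' @examples
#' expr <- parse_gpr("(g1 and g2) or g3")
#' evaluate_gpr(expr, "g3")
#' gpr_genes(expr)
#' render_gpr(expr)
#' @export
parse_gpr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  expr <- gpr_parse_or(st, text)
  if (st$pos <= nrow(st$toks)) {
    gpr_error(text, st$toks$at[st$pos],
              sprintf("unexpected token '%s'", st$toks$tok[st$pos]))
  }
  structure(expr, class = "gpr")
}

# tokenizer: identifiers, parentheses, connectives; keeps character offsets
gpr_tokenize <- function(text) {
  pat <- "\\(|\\)|&&|\\|\\||&|\\||[^\\s()&|]+"
  m <- gregexpr(pat, text, perl = TRUE)
  if (m[[1L]][1L] == -1L) gpr_error(text, 1L, "no tokens")
  tok <- regmatches(text, m)[[1L]]
  data.frame(tok = tok, at = as.integer(m[[1L]]), stringsAsFactors = FALSE)
}

gpr_error <- function(text, at, msg) {
  stop(sprintf("GPR parse error at character %d in \"%s\": %s", at, text, msg),
       call. = FALSE)
}

gpr_is_op <- function(tok, op) {
  if (op == "and") tolower(tok) %in% c("and", "&&", "&")
  else tolower(tok) %in% c("or", "||", "|")
}

gpr_peek <- function(st) if (st$pos <= nrow(st$toks)) st$toks$tok[st$pos] else NA_character_

gpr_parse_or <- function(st, text) {
  args <- list(gpr_parse_and(st, text))
  while (!is.na(tk <- gpr_peek(st)) && gpr_is_op(tk, "or")) {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st, text)))
  }
  gpr_node("or", args)
}

gpr_parse_and <- function(st, text) {
  args <- list(gpr_parse_atom(st, text))
  while (!is.na(tk <- gpr_peek(st)) && gpr_is_op(tk, "and")) {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st, text)))
  }
  gpr_node("and", args)
}

gpr_parse_atom <- function(st, text) {
  tk <- gpr_peek(st)
  if (is.na(tk)) {
    last <- st$toks$at[nrow(st$toks)]
    gpr_error(text, last, "dangling connective or empty expression")
  }
  at <- st$toks$at[st$pos]
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st, text)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")")
      gpr_error(text, at, "unbalanced parenthesis")
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk == ")" || gpr_is_op(tk, "and") || gpr_is_op(tk, "or"))
    gpr_error(text, at, sprintf("expected gene id, got '%s'", tk))
  st$pos <- st$pos + 1L
  trimws(tk)
}

# n-ary node; flattens same-op children so associativity is canonical
gpr_node <- function(op, args) {
  if (length(args) == 1L) return(args[[1L]])
  flat <- list()
  for (a in args) {
    if (is.list(a) && identical(a$op, op)) flat <- c(flat, a$args)
    else flat <- c(flat, list(a))
  }
  list(op = op, args = flat)
}

#' @rdname parse_gpr
#' @param expr a parsed `gpr` tree (or `NULL`).
#' @param present character vector of gene ids counted as present.
#' @return `evaluate_gpr()`: logical scalar. Evaluating `NULL` is an error:
#'   rules-less reactions must be handled by the caller.
#' @export
evaluate_gpr <- function(expr, present) {
  if (is.null(expr)) stop("cannot evaluate an empty GPR; handle no-rule reactions upstream")
  present <- trimws(as.character(present))
  eval_node <- function(nd) {
    if (!is.list(nd)) return(nd %in% present)
    vals <- vapply(nd$args, eval_node, logical(1L))
    if (nd$op == "and") all(vals) else any(vals)
  }
  eval_node(expr)
}

#' @rdname parse_gpr
#' @return `gpr_genes()`: sorted unique character vector of gene ids
#'   (empty for `NULL`).
#' @export
gpr_genes <- function(expr) {
  if (is.null(expr)) return(character())
  leaves <- function(nd) {
    if (!is.list(nd)) return(nd)
    unlist(lapply(nd$args, leaves), use.names = FALSE)
  }
  sort(unique(leaves(expr)))
}

#' @rdname parse_gpr
#' @return `render_gpr()`: the rule as text; `""` for `NULL`.
#' @export
render_gpr <- function(expr) {
  if (is.null(expr)) return("")
  rend <- function(nd, parent_op) {
    if (!is.list(nd)) return(nd)
    parts <- vapply(nd$args, rend, character(1L), parent_op = nd$op)
    out <- paste(parts, collapse = paste0(" ", nd$op, " "))
    # an or-node inside an and-node needs parentheses
    if (identical(nd$op, "or") && identical(parent_op, "and")) out <- paste0("(", out, ")")
    out
  }
  rend(expr, NA_character_)
}
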