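#' Parse a PubMed-style Boolean query
#'
#' Implements the filter dialect used throughout the package: field-tagged
#' terms combined with `AND`, `OR` and the binary set-difference `NOT`
#' (as in `chest pain NOT MRI`). Operator precedence is `NOT` > `AND` >
#' `OR`, left-associative; parentheses override. Supported field tags
#' (case-insensitive): `tw` (text word: title, abstract, MeSH heading and
#' subheading names), `TIAB`, `ti` (also `title`), `MeSH` (also `mesh`,
#' `mh`; `:noexp` suppresses explosion), `sh` (also `subheading`), `pt`.
#' A term without a tag defaults to `[tw]`. A trailing `*` requests
#' token-prefix truncation. Quoted strings, and unquoted multiword runs
#' immediately before a field tag, bind as a single phrase.
#'
#' @param text a single query string, e.g.
#'   `'(Diagnosis[tw] AND (specific*[tw] OR exam*[tw])) OR
#'   "sensitivity and specificity"[MeSH]'`.
#' @return an object of class `query_node`: either a term leaf (fields
#'   `term`, `field`, `truncated`, `noexp`) or a Boolean node (fields
#'   `op`, `lhs`, `rhs`).
#' @seealso [evaluate_query()], [retrieve()], [deparse_query()]
#' @export
parse_query <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text)))
    stop("query must be a non-empty string", call. = FALSE)
  toks <- lex_query(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$i <- 1L
  node <- parse_or(st)
  if (st$i <= length(st$toks)) {
    t <- st$toks[[st$i]]
    stop(sprintf("parse error at position %d: unexpected '%s'",
                 t$pos, t$text), call. = FALSE)
  }
  node
}

# --- lexer -------------------------------------------------------------

lex_query <- function(text) {
  toks <- list()
  n <- nchar(text)
  i <- 1L
  push <- function(type, text, pos, trunc = FALSE)
    toks[[length(toks) + 1L]] <<- list(type = type, text = text, pos = pos,
                                       trunc = trunc)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(") { push("lparen", "(", i); i <- i + 1L; next }
    if (ch == ")") { push("rparen", ")", i); i <- i + 1L; next }
    if (ch == "\"") {
      rest <- substr(text, i + 1L, n)
      close <- regexpr("\"", rest, fixed = TRUE)
      if (close < 0)
        stop(sprintf("parse error at position %d: unbalanced quote", i),
             call. = FALSE)
      phrase <- substr(rest, 1L, close - 1L)
      i <- i + close + 1L
      trunc <- FALSE
      if (i <= n && substr(text, i, i) == "*") { trunc <- TRUE; i <- i + 1L }
      push("phrase", phrase, i, trunc)
      next
    }
    if (ch == "[") {
      rest <- substr(text, i + 1L, n)
      close <- regexpr("]", rest, fixed = TRUE)
      if (close < 0)
        stop(sprintf("parse error at position %d: unbalanced bracket", i),
             call. = FALSE)
      push("tag", substr(rest, 1L, close - 1L), i)
      i <- i + close + 1L
      next
    }
    m <- regexpr("^[^\\s()\\[\\]\"]+", substr(text, i, n), perl = TRUE)
    word <- regmatches(substr(text, i, n), m)
    push("word", word, i)
    i <- i + attr(m, "match.length")
    next
  }
  toks
}

peek <- function(st) if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL

is_operator_word <- function(tok, op = c("AND", "OR", "NOT")) {
  !is.null(tok) && tok$type == "word" && toupper(tok$text) %in% op
}

# --- parser ------------------------------------------------------------

parse_or <- function(st) {
  left <- parse_and(st)
  while (is_operator_word(peek(st), "OR")) {
    st$i <- st$i + 1L
    left <- bool_node("OR", left, parse_and(st))
  }
  left
}

parse_and <- function(st) {
  left <- parse_not(st)
  while (is_operator_word(peek(st), "AND")) {
    st$i <- st$i + 1L
    left <- bool_node("AND", left, parse_not(st))
  }
  left
}

parse_not <- function(st) {
  left <- parse_atom(st)
  while (is_operator_word(peek(st), "NOT")) {
    st$i <- st$i + 1L
    left <- bool_node("NOT", left, parse_atom(st))
  }
  left
}

parse_atom <- function(st) {
  tok <- peek(st)
  if (is.null(tok))
    stop("parse error: unexpected end of query (empty operand)",
         call. = FALSE)
  if (is_operator_word(tok))
    stop(sprintf("parse error at position %d: operator '%s' has no left operand",
                 tok$pos, tok$text), call. = FALSE)
  if (tok$type == "lparen") {
    st$i <- st$i + 1L
    node <- parse_or(st)
    close <- peek(st)
    if (is.null(close) || close$type != "rparen")
      stop(sprintf("parse error at position %d: unbalanced parenthesis",
                   tok$pos), call. = FALSE)
    st$i <- st$i + 1L
    return(node)
  }
  if (tok$type == "phrase") {
    st$i <- st$i + 1L
    if (!nzchar(trimws(tok$text)))
      stop(sprintf("parse error at position %d: empty quoted phrase",
                   tok$pos), call. = FALSE)
    return(finish_leaf(st, tok$text, tok$trunc))
  }
  if (tok$type == "word") {
    words <- character()
    trunc <- FALSE
    while (!is.null(tok <- peek(st)) && tok$type == "word" &&
           !is_operator_word(tok)) {
      words <- c(words, tok$text)
      st$i <- st$i + 1L
    }
    last <- words[length(words)]
    if (endsWith(last, "*")) {
      trunc <- TRUE
      words[length(words)] <- sub("\\*+$", "", last)
      if (!nzchar(words[length(words)]))
        stop("parse error: bare '*' is not a term", call. = FALSE)
    }
    return(finish_leaf(st, paste(words, collapse = " "), trunc))
  }
  stop(sprintf("parse error at position %d: unexpected '%s'",
               tok$pos, tok$text), call. = FALSE)
}

finish_leaf <- function(st, term, trunc) {
  field <- "tw"
  noexp <- FALSE
  tok <- peek(st)
  if (!is.null(tok) && tok$type == "tag") {
    st$i <- st$i + 1L
    ft <- normalize_field_tag(tok$text, tok$pos)
    field <- ft$field
    noexp <- ft$noexp
  }
  term_leaf(term, field, trunc, noexp)
}

normalize_field_tag <- function(tag, pos) {
  raw <- gsub("\\s+", "", tolower(tag))
  parts <- strsplit(raw, ":", fixed = TRUE)[[1]]
  base <- parts[1]
  field <- switch(base,
    tw = "tw", tiab = "tiab", ti = "ti", title = "ti",
    mesh = "mesh", mh = "mesh",
    sh = "sh", subheading = "sh",
    pt = "pt",
    stop(sprintf("parse error at position %d: unknown field tag [%s]",
                 pos, tag), call. = FALSE))
  noexp <- FALSE
  if (length(parts) > 1L) {
    if (field != "mesh" || parts[2] != "noexp" || length(parts) > 2L)
      stop(sprintf("parse error at position %d: unknown field tag [%s]",
                   pos, tag), call. = FALSE)
    noexp <- TRUE
  }
  list(field = field, noexp = noexp)
}

term_leaf <- function(term, field = "tw", truncated = FALSE, noexp = FALSE) {
  if (!nzchar(trimws(term)))
    stop("term text must be non-empty", call. = FALSE)
  structure(list(kind = "term", term = term, field = field,
                 truncated = truncated, noexp = noexp,
                 tokens = tokenize(term)[[1]]),
            class = "query_node")
}

bool_node <- function(op, lhs, rhs) {
  structure(list(kind = "bool", op = op, lhs = lhs, rhs = rhs),
            class = "query_node")
}

#' Serialize a parsed query back to the dialect
#'
#' Re-parsing the result yields a semantically identical tree. Compound
#' operands are fully parenthesized; multiword terms are quoted.
#'
#' @param node a `query_node`.
#' @return a single query string.
#' @export
deparse_query <- function(node) {
  stopifnot(inherits(node, "query_node"))
  if (node$kind == "term") {
    term <- node$term
    if (grepl("\\s", term)) term <- paste0("\"", term, "\"")
    tag <- node$field
    tag <- switch(tag, tw = "tw", tiab = "TIAB", ti = "ti", mesh = "MeSH",
                  sh = "sh", pt = "pt")
    if (node$noexp) tag <- paste0(tag, ":noexp")
    paste0(term, if (node$truncated) "*", "[", tag, "]")
  } else {
    paste0("(", deparse_query(node$lhs), " ", node$op, " ",
           deparse_query(node$rhs), ")")
  }
}

#' @export
print.query_node <- function(x, ...) {
  cat("<query> ", deparse_query(x), "\n", sep = "")
  invisible(x)
}

# --- evaluation --------------------------------------------------------

#' Evaluate a query over every document of a corpus
#'
#' Leaf semantics: `[ti]` matches the (possibly quoted-phrase) term among
#' title tokens; `[TIAB]` in title or abstract; `[tw]` additionally in
#' MeSH heading and subheading names; `[MeSH]` is an exact
#' case-insensitive heading-name match, extended to descendant headings
#' when a hierarchy is supplied and the leaf is not `noexp`; `[sh]`
#' matches attached subheading names; `[pt]` publication types. A
#' truncated term matches as a token prefix. `AND`/`OR` are intersection
#' and union; `NOT` is left minus right.
#'
#' @param corpus a `bib_corpus` or `labeled_corpus`.
#' @param node a parsed `query_node` (or a query string, parsed on the fly).
#' @param hierarchy optional [read_mesh_hierarchy()] object enabling MeSH
#'   explosion; without it no explosion occurs.
#' @return logical vector in corpus order.
#' @export
query_matches <- function(corpus, node, hierarchy = NULL) {
  if (inherits(corpus, "labeled_corpus")) corpus <- corpus$corpus
  if (is.character(node)) node <- parse_query(node)
  stopifnot(inherits(node, "query_node"))
  eval_node(corpus$index, length(corpus$docs), node, hierarchy)
}

eval_node <- function(index, n, node, hierarchy) {
  if (node$kind == "bool") {
    l <- eval_node(index, n, node$lhs, hierarchy)
    r <- eval_node(index, n, node$rhs, hierarchy)
    return(switch(node$op, AND = l & r, OR = l | r, NOT = l & !r))
  }
  switch(node$field,
    ti = token_field_match(index$title_tokens, node),
    tiab = token_field_match(index$title_tokens, node) |
           token_field_match(index$abstract_tokens, node),
    tw = token_field_match(index$title_tokens, node) |
         token_field_match(index$abstract_tokens, node) |
         token_field_match(index$mesh_tokens, node),
    mesh = mesh_field_match(index$mesh_names, node, hierarchy),
    sh = name_field_match(index$subheadings, node),
    pt = name_field_match(index$pub_types, node))
}

token_field_match <- function(token_lists, leaf) {
  phrase <- leaf$tokens
  if (!length(phrase)) return(vapply(token_lists, function(t) FALSE, logical(1)))
  vapply(token_lists, phrase_in_tokens, logical(1),
         phrase = phrase, trunc = leaf$truncated)
}

phrase_in_tokens <- function(tokens, phrase, trunc) {
  np <- length(phrase)
  nt <- length(tokens)
  if (nt < np) return(FALSE)
  if (np == 1L) {
    if (trunc) return(any(startsWith(tokens, phrase)))
    return(phrase %in% tokens)
  }
  starts <- which(tokens == phrase[1L])
  starts <- starts[starts <= nt - np + 1L]
  for (s in starts) {
    seg <- tokens[s:(s + np - 1L)]
    head_ok <- all(seg[-np] == phrase[-np])
    tail_ok <- if (trunc) startsWith(seg[np], phrase[np]) else
      seg[np] == phrase[np]
    if (head_ok && tail_ok) return(TRUE)
  }
  FALSE
}

name_field_match <- function(name_lists, leaf) {
  target <- normalize_name(leaf$term)
  if (leaf$truncated)
    vapply(name_lists, function(v) any(startsWith(v, target)), logical(1))
  else
    vapply(name_lists, function(v) target %in% v, logical(1))
}

mesh_field_match <- function(name_lists, leaf, hierarchy) {
  target <- normalize_name(leaf$term)
  targets <- target
  if (!is.null(hierarchy) && !leaf$noexp)
    targets <- c(target, mesh_descendants(hierarchy, target))
  if (leaf$truncated)
    vapply(name_lists, function(v)
      any(vapply(targets, function(tg) any(startsWith(v, tg)), logical(1))),
      logical(1))
  else
    vapply(name_lists, function(v) any(targets %in% v), logical(1))
}

#' Evaluate a query against a single document
#'
#' @param doc a [document()].
#' @inheritParams query_matches
#' @return `TRUE` or `FALSE`.
#' @export
evaluate_query <- function(doc, node, hierarchy = NULL) {
  stopifnot(inherits(doc, "bib_document"))
  query_matches(bib_corpus(list(doc)), node, hierarchy)[[1]]
}

#' Retrieve the document set matching a query
#'
#' @inheritParams query_matches
#' @return character vector of matching doc_ids (a set, in corpus order).
#' @export
retrieve <- function(corpus, node, hierarchy = NULL) {
  ids <- corpus_ids(corpus)
  ids[query_matches(corpus, node, hierarchy)]
}

# --- MeSH hierarchy ----------------------------------------------------

#' Read a MeSH hierarchy for explosion
#'
#' Two-column text file, `child <tab> parent` (whitespace also accepted),
#' one edge per line; `#` comments and blank lines ignored. Explosion of a
#' `[MeSH]` leaf includes all descendants of the heading. No hierarchy
#' ships with the package: explosion is strictly opt-in.
#'
#' @param file path or connection.
#' @param text optional character vector of lines.
#' @return an object of class `mesh_hierarchy` (parent -> children map).
#' @export
read_mesh_hierarchy <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else read_text_lines(file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  # tab-separated preferred (heading names may contain single spaces);
  # runs of >= 2 spaces accepted as a separator variant
  parts <- lapply(lines, function(l) {
    p <- if (grepl("\t", l)) strsplit(l, "\t+")[[1]]
         else strsplit(l, "\\s{2,}")[[1]]
    trimws(p[nzchar(trimws(p))])
  })
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad))
    stop("malformed hierarchy line ", bad[1],
         ": need 'child<TAB>parent'", call. = FALSE)
  child <- normalize_name(vapply(parts, `[`, character(1), 1L))
  parent <- normalize_name(vapply(parts, `[`, character(1), 2L))
  structure(split(child, parent), class = "mesh_hierarchy")
}

#' @rdname read_mesh_hierarchy
#' @param hierarchy a `mesh_hierarchy`.
#' @param heading heading name whose descendants are wanted.
#' @return for `mesh_descendants`, a character vector of descendant
#'   heading names (normalized lowercase), excluding the heading itself.
#' @export
mesh_descendants <- function(hierarchy, heading) {
  stopifnot(inherits(hierarchy, "mesh_hierarchy"))
  seen <- character()
  frontier <- normalize_name(heading)
  while (length(frontier)) {
    kids <- unique(unlist(unname(hierarchy[frontier]), use.names = FALSE))
    kids <- setdiff(kids, c(seen, normalize_name(heading)))
    seen <- c(seen, kids)
    frontier <- kids
  }
  seen
}
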