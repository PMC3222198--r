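`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tokenize free text for query matching
#'
#' Case-folds and splits on any non-alphanumeric character; empty tokens are
#' dropped. No stemming is applied: truncation is only ever explicit, via a
#' trailing `*` in a query term.
#'
#' @param x character vector.
#' @return list of character vectors, one per element of `x`.
#' @keywords internal
tokenize <- function(x) {
  x <- tolower(as.character(x))
  out <- strsplit(x, "[^a-z0-9]+")
  lapply(out, function(t) t[nzchar(t)])
}

# collapse internal whitespace and case-fold, for exact-name fields
# ([MeSH], [sh], [pt])
normalize_name <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

read_text_lines <- function(file) {
  if (inherits(file, "connection")) return(readLines(file, warn = FALSE))
  if (!is.character(file) || length(file) != 1L)
    stop("`file` must be a path or a connection", call. = FALSE)
  readLines(file, warn = FALSE)
}
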