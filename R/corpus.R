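#' Construct a bibliographic document
#'
#' One MEDLINE-style record: title, abstract, MeSH headings (with attached
#' subheadings and a major-topic flag), and publication types. These are the
#' fields the query engine's tags (`[ti]`, `[TIAB]`, `[tw]`, `[MeSH]`,
#' `[sh]`, `[pt]`) search.
#'
#' @param doc_id unique identifier (PMID-like string).
#' @param title title text (may be empty).
#' @param abstract abstract text; may be empty — records without abstracts
#'   are retained and searchable.
#' @param mesh list of MeSH headings, each a list with elements `heading`
#'   (string), `subheadings` (character vector, possibly empty) and `major`
#'   (logical major-topic flag).
#' @param pub_types character vector of publication type names.
#' @param year integer publication year or `NA`.
#' @param journal journal title or `NA`.
#' @return an object of class `bib_document`.
#' @export
document <- function(doc_id, title = "", abstract = "", mesh = list(),
                     pub_types = character(), year = NA_integer_,
                     journal = NA_character_) {
  doc_id <- as.character(doc_id)
  if (length(doc_id) != 1L || is.na(doc_id) || !nzchar(doc_id))
    stop("doc_id must be a non-empty string", call. = FALSE)
  mesh <- lapply(mesh, function(m) {
    if (is.character(m)) m <- list(heading = m)
    heading <- as.character(m$heading %||% m[[1]])
    if (!nzchar(heading)) stop("MeSH heading name must be non-empty", call. = FALSE)
    sub <- as.character(m$subheadings %||% character())
    if (any(!nzchar(sub))) stop("MeSH subheading names must be non-empty", call. = FALSE)
    list(heading = heading, subheadings = sub,
         major = isTRUE(m$major))
  })
  structure(
    list(doc_id = doc_id, title = as.character(title),
         abstract = as.character(abstract), mesh = mesh,
         pub_types = as.character(pub_types),
         year = as.integer(year), journal = as.character(journal)),
    class = "bib_document")
}

#' Construct a corpus of bibliographic documents
#'
#' Validates ID uniqueness and builds the token index used by
#' [query_matches()]. Corpora are treated as immutable: the index is built
#' once, at construction.
#'
#' @param docs list of [document()] objects.
#' @return an object of class `bib_corpus`.
#' @export
bib_corpus <- function(docs) {
  if (!is.list(docs)) stop("docs must be a list of documents", call. = FALSE)
  ids <- vapply(docs, function(d) d$doc_id, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate doc_id in corpus: ", paste(dup, collapse = ", "),
         call. = FALSE)
  corpus <- structure(list(docs = docs, ids = ids), class = "bib_corpus")
  corpus$index <- build_index(docs)
  corpus
}

# Per-document lowercase token lists and name sets, precomputed once.
build_index <- function(docs) {
  titles <- vapply(docs, function(d) d$title, character(1))
  abstracts <- vapply(docs, function(d) d$abstract, character(1))
  mesh_names <- lapply(docs, function(d)
    vapply(d$mesh, function(m) normalize_name(m$heading), character(1)))
  subheadings <- lapply(docs, function(d)
    normalize_name(unlist(lapply(d$mesh, function(m) m$subheadings),
                          use.names = FALSE) %||% character()))
  mesh_text <- vapply(seq_along(docs), function(i)
    paste(c(mesh_names[[i]], subheadings[[i]]), collapse = " . "),
    character(1))
  list(
    title_tokens = tokenize(titles),
    abstract_tokens = tokenize(abstracts),
    mesh_tokens = tokenize(mesh_text),
    mesh_names = mesh_names,
    subheadings = subheadings,
    pub_types = lapply(docs, function(d) normalize_name(d$pub_types))
  )
}

#' @export
print.bib_corpus <- function(x, ...) {
  cat("<bib_corpus> ", length(x$docs), " documents\n", sep = "")
  invisible(x)
}

#' @export
length.bib_corpus <- function(x) length(x$docs)

#' Document identifiers of a corpus
#' @param corpus a `bib_corpus` or `labeled_corpus`.
#' @return character vector of doc_ids in corpus order.
#' @export
corpus_ids <- function(corpus) {
  if (inherits(corpus, "labeled_corpus")) corpus <- corpus$corpus
  corpus$ids
}

#' Which documents carry a non-empty abstract?
#' @inheritParams corpus_ids
#' @return logical vector in corpus order.
#' @export
has_abstract <- function(corpus) {
  if (inherits(corpus, "labeled_corpus")) corpus <- corpus$corpus
  vapply(corpus$docs, function(d) nzchar(trimws(d$abstract)), logical(1))
}

#' Subset a corpus by position or ID
#' @param corpus a `bib_corpus`.
#' @param keep logical vector, integer positions, or character doc_ids.
#' @return a new `bib_corpus`.
#' @export
subset_corpus <- function(corpus, keep) {
  if (is.character(keep)) {
    miss <- setdiff(keep, corpus$ids)
    if (length(miss))
      stop("unknown doc_id: ", paste(miss, collapse = ", "), call. = FALSE)
    keep <- match(keep, corpus$ids)
  }
  bib_corpus(corpus$docs[keep])
}

#' Attach a gold standard to a corpus
#'
#' A labeled corpus pairs documents with the set of IDs judged relevant
#' (the gold standard a filter should retrieve). Prevalence must lie
#' strictly between 0 and 1: a gold standard with no relevant (or no
#' nonrelevant) documents makes recall (or fallout) meaningless.
#'
#' @param corpus a `bib_corpus`.
#' @param relevant_ids character vector of gold-standard doc_ids.
#' @return an object of class `labeled_corpus` with elements `corpus` and
#'   `relevant_ids`.
#' @export
labeled_corpus <- function(corpus, relevant_ids) {
  stopifnot(inherits(corpus, "bib_corpus"))
  relevant_ids <- unique(as.character(relevant_ids))
  unknown <- setdiff(relevant_ids, corpus$ids)
  if (length(unknown))
    stop("relevant IDs not present in corpus: ",
         paste(utils::head(unknown, 10), collapse = ", "),
         if (length(unknown) > 10) " ...", call. = FALSE)
  n <- length(corpus$docs)
  k <- length(relevant_ids)
  if (k == 0L)
    stop("degenerate corpus: no relevant documents (recall undefined)",
         call. = FALSE)
  if (k == n)
    stop("degenerate corpus: every document is relevant (fallout undefined)",
         call. = FALSE)
  structure(list(corpus = corpus, relevant_ids = relevant_ids),
            class = "labeled_corpus")
}

#' @export
print.labeled_corpus <- function(x, ...) {
  cat(sprintf("<labeled_corpus> %d documents, %d relevant (prevalence %.4g)\n",
              length(x$corpus$docs), length(x$relevant_ids), prevalence(x)))
  invisible(x)
}

#' Gold-standard prevalence of a labeled corpus
#' @param x a `labeled_corpus`.
#' @return fraction of documents that are relevant.
#' @export
prevalence <- function(x) {
  stopifnot(inherits(x, "labeled_corpus"))
  length(x$relevant_ids) / length(x$corpus$docs)
}

# logical relevance vector in corpus order
relevance_vector <- function(x) {
  x$corpus$ids %in% x$relevant_ids
}

#' Load a gold-standard label list
#'
#' Reads one doc_id per line (blank lines and `#` comments ignored) and
#' attaches it to a corpus.
#'
#' @param file path, connection, or (with `text`) inline lines.
#' @param corpus the `bib_corpus` the labels refer to.
#' @param text optional character vector of lines, instead of `file`.
#' @return a [labeled_corpus()].
#' @export
load_labels <- function(file = NULL, corpus, text = NULL) {
  lines <- if (!is.null(text)) text else read_text_lines(file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    stop("empty label list: a gold standard of zero relevant documents ",
         "makes recall undefined", call. = FALSE)
  ids <- unique(lines)
  unknown <- setdiff(ids, corpus$ids)
  if (length(unknown))
    stop("label list contains IDs absent from the corpus: ",
         paste(utils::head(unknown, 10), collapse = ", "),
         if (length(unknown) > 10) " ...", call. = FALSE)
  labeled_corpus(corpus, ids)
}
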