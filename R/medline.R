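#' Read a MEDLINE flat file
#'
#' Parses the 4-character-tag format exported by PubMed (`TAG - value`,
#' continuation lines indented) into documents. A tab after the tag is
#' accepted as a separator variant, and a blank line separates records.
#' Tags used: `PMID`, `TI`, `AB`, `MH`, `PT`, `DP` (year), `JT`; others are
#' carried past. `MH` values are split at `/` into the heading and its
#' subheadings, and a leading `*` (on the heading or a subheading) is
#' stripped into the major-topic flag.
#'
#' @param file path or connection.
#' @param text optional character vector of lines, instead of `file`.
#' @return a [bib_corpus()].
#' @examples
#' rec <- c("PMID- 1", "TI  - Accuracy of the clinical exam.",
#'          "MH  - *Heart Failure/diagnosis", "PT  - Journal Article", "")
#' read_medline(text = rec)
#' @export
read_medline <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else read_text_lines(file)
  records <- list()
  fields <- list()   # list of c(tag, value)
  cur_tag <- NULL

  flush_record <- function() {
    if (length(fields)) records[[length(records) + 1L]] <<- fields
    fields <<- list()
    cur_tag <<- NULL
  }

  tag_re <- "^([A-Z][A-Z0-9]{0,3}) *- (.*)$"
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) { flush_record(); next }
    if (grepl(tag_re, line)) {
      cur_tag <- sub(tag_re, "\\1", line)
      fields[[length(fields) + 1L]] <- c(cur_tag, sub(tag_re, "\\2", line))
    } else if (grepl("^([A-Z][A-Z0-9]{0,3})\t", line)) {
      cur_tag <- sub("^([A-Z][A-Z0-9]{0,3})\t.*$", "\\1", line)
      fields[[length(fields) + 1L]] <-
        c(cur_tag, sub("^[A-Z][A-Z0-9]{0,3}\t", "", line))
    } else if (grepl("^[ \t]", line) && !is.null(cur_tag)) {
      k <- length(fields)
      fields[[k]][2] <- paste(fields[[k]][2], trimws(line))
    } else {
      stop(sprintf("malformed MEDLINE tag line at line %d: %s", i,
                   substr(line, 1, 40)), call. = FALSE)
    }
  }
  flush_record()

  docs <- lapply(records, medline_record_to_document)
  ids <- vapply(docs, function(d) d$doc_id, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate PMID in MEDLINE input: ", paste(dup, collapse = ", "),
         call. = FALSE)
  bib_corpus(docs)
}

medline_record_to_document <- function(fields) {
  tags <- vapply(fields, `[`, character(1), 1L)
  vals <- vapply(fields, `[`, character(1), 2L)
  get1 <- function(tag) {
    v <- vals[tags == tag]
    if (length(v)) v[[1]] else ""
  }
  pmid <- trimws(get1("PMID"))
  if (!nzchar(pmid)) stop("MEDLINE record without PMID", call. = FALSE)
  mesh <- lapply(vals[tags == "MH"], parse_mh_value)
  dp <- get1("DP")
  year <- if (grepl("\\b([0-9]{4})\\b", dp))
    as.integer(regmatches(dp, regexpr("[0-9]{4}", dp))) else NA_integer_
  document(
    doc_id = pmid,
    title = get1("TI"),
    abstract = get1("AB"),
    mesh = mesh,
    pub_types = as.character(vals[tags == "PT"]),
    year = year,
    journal = if (nzchar(get1("JT"))) get1("JT") else NA_character_
  )
}

parse_mh_value <- function(value) {
  parts <- strsplit(value, "/", fixed = TRUE)[[1]]
  major <- any(startsWith(parts, "*"))
  parts <- sub("^\\*", "", trimws(parts))
  list(heading = parts[[1]],
       subheadings = if (length(parts) > 1L) parts[-1L] else character(),
       major = major)
}

#' Write a corpus as a MEDLINE flat file
#'
#' Inverse of [read_medline()] for the fields the query engine searches;
#' `read_medline(write_medline(x))` reproduces titles, abstracts, MeSH
#' headings/subheadings with major-topic flags, and publication types.
#'
#' @param corpus a `bib_corpus` (or `labeled_corpus`, whose documents are
#'   written).
#' @param file path or connection; omit to return the lines invisibly.
#' @return invisibly, the character vector of lines written.
#' @export
write_medline <- function(corpus, file = NULL) {
  if (inherits(corpus, "labeled_corpus")) corpus <- corpus$corpus
  fmt <- function(tag, value) sprintf("%-4s- %s", tag, value)
  out <- unlist(lapply(corpus$docs, function(d) {
    lines <- fmt("PMID", d$doc_id)
    if (nzchar(d$title)) lines <- c(lines, fmt("TI", d$title))
    if (nzchar(d$abstract)) lines <- c(lines, fmt("AB", d$abstract))
    for (m in d$mesh) {
      v <- paste(c(m$heading, m$subheadings), collapse = "/")
      if (m$major) v <- paste0("*", v)
      lines <- c(lines, fmt("MH", v))
    }
    for (pt in d$pub_types) lines <- c(lines, fmt("PT", pt))
    if (!is.na(d$year)) lines <- c(lines, fmt("DP", as.character(d$year)))
    if (!is.na(d$journal)) lines <- c(lines, fmt("JT", d$journal))
    c(lines, "")
  }), use.names = FALSE)
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

#' Read/write the line-delimited structured record format
#'
#' The native fixture format: one JSON object per line with keys `doc_id`,
#' `title`, `abstract`, `mesh` (array of `{heading, subheadings, major}`),
#' `pub_types`, `year`, `journal`. Fast and diff-friendly.
#'
#' @param file path or connection.
#' @param text optional character vector of lines.
#' @return a [bib_corpus()].
#' @export
read_corpus_jsonl <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else read_text_lines(file)
  lines <- lines[nzchar(trimws(lines))]
  docs <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE,
                         simplifyDataFrame = FALSE, simplifyMatrix = FALSE),
      error = function(e) stop(sprintf("bad JSON record at line %d: %s",
                                       i, conditionMessage(e)), call. = FALSE))
    document(doc_id = rec$doc_id,
             title = rec$title %||% "",
             abstract = rec$abstract %||% "",
             mesh = rec$mesh %||% list(),
             pub_types = unlist(rec$pub_types) %||% character(),
             year = rec$year %||% NA_integer_,
             journal = rec$journal %||% NA_character_)
  })
  bib_corpus(docs)
}

#' @rdname read_corpus_jsonl
#' @param corpus a `bib_corpus` or `labeled_corpus`.
#' @export
write_corpus_jsonl <- function(corpus, file = NULL) {
  if (inherits(corpus, "labeled_corpus")) corpus <- corpus$corpus
  out <- vapply(corpus$docs, function(d) {
    rec <- list(doc_id = d$doc_id, title = d$title, abstract = d$abstract,
                mesh = lapply(d$mesh, function(m)
                  list(heading = m$heading,
                       subheadings = as.list(m$subheadings),
                       major = m$major)),
                pub_types = as.list(d$pub_types))
    if (!is.na(d$year)) rec$year <- d$year
    if (!is.na(d$journal)) rec$journal <- d$journal
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
  }, character(1))
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}
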