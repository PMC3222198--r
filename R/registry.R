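#' Built-in clinical-examination filter strings
#'
#' The named filters for retrieving clinical examination studies from
#' MEDLINE that this package's methods were designed around: the best
#' single-term filters by recall and by precision, the best OR-combination
#' filters over diagnosis-only and clinical-examination-only term slates,
#' and the multi-term filter induced by recursive partitioning. Names
#' follow the "FirstAuthor-Year[-Variant]" convention used for published
#' hedges; these package-developed filters carry descriptive names
#' instead. Every definition parses under [parse_query()].
#'
#' @return data frame of class `filter_set` with columns `name`, `query`,
#'   `provenance`.
#' @examples
#' f <- builtin_filters()
#' f$query[f$name == "RP-filter"]
#' @export
builtin_filters <- function() {
  defs <- data.frame(
    name = c("Diagnosis-subheading", "MedicalHistoryTaking-MeSH",
             "Dx-high-recall", "Dx-precise", "CE-high-recall",
             "CE-precise", "RP-filter"),
    query = c(
      "diagnosis[subheading]",
      "Medical history taking[MeSH]",
      "Diagnosis[tw] OR \"sensitivity and specificity\"[MeSH]",
      "Predictive value of tests[mesh] OR specificity[TIAB]",
      paste("Clinical*[tw] OR symptom*[tw] OR exam*[tw] OR criteria[tw]",
            "OR tests[tw] OR test[tw]"),
      "Tests[tw] OR physical[tw]",
      paste("(Diagnosis[tw] AND (specific*[tw] OR clinical*[tw] OR",
            "exam*[tw])) OR \"sensitivity and specificity\"[MeSH]")),
    provenance = c(
      "best single-term recall",
      "best single-term precision and F-measure",
      "best recall, diagnosis-term OR-combinations",
      "best precision and F-measure, diagnosis-term OR-combinations",
      "best recall, clinical-examination-term OR-combinations",
      "best precision and F-measure, clinical-examination-term OR-combinations",
      "best overall multi-term filter from recursive partitioning"),
    stringsAsFactors = FALSE)
  class(defs) <- c("filter_set", "data.frame")
  defs
}

#' Load filter definitions from a tab-separated file
#'
#' Format: `name <TAB> query [<TAB> provenance]`, one filter per line;
#' blank lines and `#` comments ignored. Every query must parse; duplicate
#' names are rejected. This is the vehicle for user-supplied filter sets
#' such as previously published diagnosis hedges.
#'
#' @param file path or connection.
#' @param text optional character vector of lines.
#' @return a `filter_set` data frame (`name`, `query`, `provenance`).
#' @export
load_filters <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else read_text_lines(file)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines))
    return(structure(data.frame(name = character(), query = character(),
                                provenance = character(),
                                stringsAsFactors = FALSE),
                     class = c("filter_set", "data.frame")))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad))
    stop("malformed filter definition at line ", bad[1],
         ": need 'name<TAB>query'", call. = FALSE)
  name <- trimws(vapply(parts, `[`, character(1), 1L))
  query <- trimws(vapply(parts, `[`, character(1), 2L))
  prov <- trimws(vapply(parts, function(p)
    if (length(p) >= 3L) p[[3]] else "", character(1)))
  dup <- unique(name[duplicated(name)])
  if (length(dup))
    stop("duplicate filter names: ", paste(dup, collapse = ", "),
         call. = FALSE)
  for (i in seq_along(query)) {
    tryCatch(parse_query(query[[i]]), error = function(e)
      stop(sprintf("filter '%s' does not parse: %s", name[[i]],
                   conditionMessage(e)), call. = FALSE))
  }
  structure(data.frame(name = name, query = query, provenance = prov,
                       stringsAsFactors = FALSE),
            class = c("filter_set", "data.frame"))
}

#' Write filter definitions to a tab-separated file
#'
#' Inverse of [load_filters()].
#'
#' @param filters a `filter_set` (or data frame with `name` and `query`,
#'   optionally `provenance`).
#' @param file path or connection; omit to return lines invisibly.
#' @return invisibly, the lines written.
#' @export
write_filters <- function(filters, file = NULL) {
  stopifnot(is.data.frame(filters),
            all(c("name", "query") %in% names(filters)))
  prov <- filters$provenance %||% rep("", nrow(filters))
  out <- ifelse(nzchar(prov),
                paste(filters$name, filters$query, prov, sep = "\t"),
                paste(filters$name, filters$query, sep = "\t"))
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}
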