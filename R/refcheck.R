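#' Build a citation graph
#'
#' Maps each citing document to the set of documents in its reference
#' list. Endpoints need not all be corpus members; references outside the
#' corpus are simply never recoverable by augmentation.
#'
#' @param edges a data frame (or two-column matrix) with columns
#'   `citing_id`, `cited_id`, or a named list mapping citing IDs to
#'   character vectors of cited IDs.
#' @return an object of class `citation_graph`.
#' @export
citation_graph <- function(edges) {
  if (is.list(edges) && !is.data.frame(edges)) {
    g <- lapply(edges, as.character)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (ncol(edges) < 2)
      stop("edge list needs two columns: citing_id, cited_id",
           call. = FALSE)
    g <- split(as.character(edges[[2]]), as.character(edges[[1]]))
  }
  structure(lapply(g, unique), class = "citation_graph")
}

#' Read a citation graph from a two-column edge list
#'
#' One `citing_id <TAB> cited_id` pair per line (whitespace also
#' accepted); blank lines and `#` comments ignored.
#'
#' @param file path or connection.
#' @param text optional character vector of lines.
#' @return a [citation_graph()].
#' @export
read_citation_graph <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else read_text_lines(file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[\t ]+")
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad))
    stop("malformed citation edge at line ", bad[1],
         ": need 'citing_id cited_id'", call. = FALSE)
  citing <- vapply(parts, `[`, character(1), 1L)
  cited <- vapply(parts, `[`, character(1), 2L)
  citation_graph(data.frame(citing_id = citing, cited_id = cited,
                            stringsAsFactors = FALSE))
}

#' Recall gained by checking reference lists
#'
#' Emulates the reviewer's snowballing step: the reference lists of the
#' relevant articles a filter did retrieve are checked, and any relevant
#' article found there is added to the retrieved set. By default one
#' augmentation round is performed, only retrieved *relevant* documents'
#' reference lists are followed, and only relevant referenced documents
#' are added — so recall and precision can only improve.
#'
#' @param corpus a `labeled_corpus`.
#' @param retrieved character vector of retrieved doc_ids.
#' @param graph a [citation_graph()].
#' @param follow `"relevant"` (default) follows references of retrieved
#'   relevant documents only; `"all"` follows every retrieved document.
#' @param add_only_relevant if `TRUE` (default) only relevant referenced
#'   documents are added; `FALSE` adds any referenced corpus document.
#' @param transitive if `TRUE`, repeat rounds to a fixpoint
#'   (snowballing closure); default is a single round.
#' @return a list of class `ref_augmentation`: `retrieved` (augmented
#'   set), `recovered` (newly added doc_ids), `recall_before`,
#'   `recall_after` (percent, full precision).
#' @export
augment_with_references <- function(corpus, retrieved, graph,
                                    follow = c("relevant", "all"),
                                    add_only_relevant = TRUE,
                                    transitive = FALSE) {
  stopifnot(inherits(corpus, "labeled_corpus"),
            inherits(graph, "citation_graph"))
  follow <- match.arg(follow)
  retrieved <- unique(as.character(retrieved))
  before <- compute_metrics(build_contingency(corpus, retrieved))$recall
  rel <- corpus$relevant_ids
  all_ids <- corpus$corpus$ids

  current <- retrieved
  repeat {
    seeds <- if (follow == "relevant") intersect(current, rel) else current
    refs <- unique(unlist(unname(graph[intersect(seeds, names(graph))]),
                          use.names = FALSE))
    add <- intersect(refs, if (add_only_relevant) rel else all_ids)
    add <- setdiff(add, current)
    if (!length(add)) break
    current <- c(current, add)
    if (!transitive) break
  }
  after <- compute_metrics(build_contingency(corpus, current))$recall
  structure(list(retrieved = current,
                 recovered = setdiff(current, retrieved),
                 recall_before = before, recall_after = after),
            class = "ref_augmentation")
}

#' @export
print.ref_augmentation <- function(x, ...) {
  cat(sprintf(
    "reference-list augmentation: recall %.4g%% -> %.4g%% (%d recovered)\n",
    x$recall_before, x$recall_after, length(x$recovered)))
  invisible(x)
}
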