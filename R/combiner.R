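#' Score candidate single-term filters against a labeled corpus
#'
#' Parses each query string, caches its retrieval vector, and computes its
#' metrics. The cached vectors make subsequent screening, combination
#' enumeration and tree growth cheap: an OR-combination's retrieval set is
#' the union of its members' cached sets, never a re-evaluation.
#'
#' @param queries character vector of query strings in the filter dialect;
#'   names, if present, become the candidate labels (default: the query
#'   string itself).
#' @param corpus a `labeled_corpus`.
#' @param hierarchy optional MeSH hierarchy for explosion.
#' @return a list of class `candidate_set`; each element has `label`,
#'   `node` (parsed query), `matches` (logical vector over the corpus) and
#'   `metrics` (a `metrics_report`).
#' @export
candidate_terms <- function(queries, corpus, hierarchy = NULL) {
  stopifnot(inherits(corpus, "labeled_corpus"))
  queries <- as.character(queries)
  labels <- names(queries) %||% queries
  labels[!nzchar(labels)] <- queries[!nzchar(labels)]
  if (anyDuplicated(labels))
    stop("candidate labels must be unique", call. = FALSE)
  rel <- relevance_vector(corpus)
  out <- lapply(seq_along(queries), function(i) {
    node <- parse_query(queries[[i]])
    matches <- query_matches(corpus, node, hierarchy)
    list(label = labels[[i]], node = node, matches = matches,
         metrics = compute_metrics(table_from_logical(matches, rel)))
  })
  structure(out, class = "candidate_set")
}

table_from_logical <- function(matches, rel) {
  contingency_table(a = sum(matches & rel), b = sum(matches & !rel),
                    c = sum(!matches & rel), d = sum(!matches & !rel))
}

#' Tabulate a candidate set
#' @param candidates a `candidate_set`.
#' @return data frame with one row per candidate (label and raw metrics).
#' @export
candidate_table <- function(candidates) {
  stopifnot(inherits(candidates, "candidate_set"))
  do.call(rbind, lapply(candidates, function(cd)
    cbind(data.frame(label = cd$label, stringsAsFactors = FALSE),
          as.data.frame(cd$metrics))))
}

#' @export
print.candidate_set <- function(x, ...) {
  print(candidate_table(x))
  invisible(x)
}

#' Screen candidate terms by recall and fallout thresholds
#'
#' In `"and"` mode a candidate passes when recall exceeds `min_recall`
#' *and* fallout stays below `max_fallout` (the screen used before
#' exhaustive combination search, e.g. recall > 25 and fallout < 50). In
#' `"or"` mode either condition suffices (the looser screen feeding
#' recursive partitioning, e.g. recall > 25 or fallout < 75). Input order
#' is preserved.
#'
#' @param candidates a `candidate_set` from [candidate_terms()].
#' @param min_recall,max_fallout thresholds in percent, `[0, 100]`.
#' @param mode `"and"` or `"or"`.
#' @return the passing subset, still a `candidate_set`.
#' @export
screen_terms <- function(candidates, min_recall = 25, max_fallout = 50,
                         mode = c("and", "or")) {
  stopifnot(inherits(candidates, "candidate_set"))
  mode <- match.arg(mode)
  if (min_recall < 0 || min_recall > 100 || max_fallout < 0 ||
      max_fallout > 100)
    stop("thresholds must lie in [0, 100]", call. = FALSE)
  keep <- vapply(candidates, function(cd) {
    hi_recall <- cd$metrics$recall > min_recall
    lo_fallout <- !is.na(cd$metrics$fallout) &&
      cd$metrics$fallout < max_fallout
    if (mode == "and") hi_recall && lo_fallout else hi_recall || lo_fallout
  }, logical(1))
  structure(candidates[keep], class = "candidate_set")
}

#' Exhaustively score OR-combinations of screened terms
#'
#' Every subset of size `k_min` to `k_max` is scored as the OR of its
#' members, using unions of the cached per-term retrieval vectors. A
#' configurable subset cap guards against accidental exponential blowups
#' (exhaustive search over large slates is exactly what tree induction
#' replaces).
#'
#' @param candidates a `candidate_set` (typically post-[screen_terms()]).
#' @param k_min,k_max subset size range, `1 <= k_min <= k_max <= length()`.
#' @param corpus the `labeled_corpus` the candidates were scored on.
#' @param max_subsets hard cap on the number of subsets (default 1e6).
#' @return data frame of class `or_combinations`: columns `k`, `label`
#'   (members joined by `" OR "`), the raw metrics, and a list column
#'   `members` of member indices into `candidates`.
#' @export
enumerate_or_combinations <- function(candidates, k_min, k_max, corpus,
                                      max_subsets = 1e6) {
  stopifnot(inherits(candidates, "candidate_set"),
            inherits(corpus, "labeled_corpus"))
  n <- length(candidates)
  if (!(k_min >= 1 && k_min <= k_max && k_max <= n))
    stop("need 1 <= k_min <= k_max <= number of candidates", call. = FALSE)
  total <- sum(choose(n, k_min:k_max))
  if (total > max_subsets)
    stop(sprintf("combination budget exceeded: %.0f subsets > cap %.0f",
                 total, max_subsets), call. = FALSE)
  rel <- relevance_vector(corpus)
  labels <- vapply(candidates, `[[`, character(1), "label")
  rows <- vector("list", total)
  members <- vector("list", total)
  r <- 0L
  for (k in k_min:k_max) {
    combs <- utils::combn(n, k)
    for (ci in seq_len(ncol(combs))) {
      idx <- combs[, ci]
      u <- Reduce(`|`, lapply(idx, function(j) candidates[[j]]$matches))
      met <- compute_metrics(table_from_logical(u, rel))
      r <- r + 1L
      rows[[r]] <- cbind(
        data.frame(k = k, label = paste(labels[idx], collapse = " OR "),
                   stringsAsFactors = FALSE),
        as.data.frame(met))
      members[[r]] <- idx
    }
  }
  out <- do.call(rbind, rows)
  out$members <- members
  class(out) <- c("or_combinations", "data.frame")
  out
}

#' Select the best filter combination under an objective
#'
#' Objectives mirror the usual filter-development table: best recall
#' subject to a fallout cap, best precision subject to a recall floor, or
#' best F-measure unconstrained. Ties break deterministically: higher
#' recall first, then lower fallout, then the lexicographically smallest
#' sorted member-label tuple — so the result is invariant to input order.
#'
#' @param scored an `or_combinations` data frame (or any data frame with
#'   `recall`, `precision`, `f_measure`, `fallout`, `label` columns).
#' @param objective `"recall"`, `"precision"` or `"f"`.
#' @param fallout_cap fallout must stay below this for `"recall"` (default
#'   50).
#' @param recall_floor recall must exceed this for `"precision"` (default
#'   50).
#' @return the single winning row.
#' @export
select_best <- function(scored, objective = c("f", "recall", "precision"),
                        fallout_cap = 50, recall_floor = 50) {
  objective <- match.arg(objective)
  ok <- switch(objective,
    recall = !is.na(scored$fallout) & scored$fallout < fallout_cap,
    precision = scored$recall > recall_floor,
    f = rep(TRUE, nrow(scored)))
  ok[is.na(ok)] <- FALSE
  pool <- scored[ok, , drop = FALSE]
  if (!nrow(pool))
    stop("no combination satisfies the '", objective, "' constraint",
         call. = FALSE)
  key <- switch(objective, recall = pool$recall,
                precision = pool$precision, f = pool$f_measure)
  key[is.na(key)] <- -Inf
  tie_label <- vapply(strsplit(pool$label, " OR ", fixed = TRUE),
                      function(p) paste(sort(p), collapse = " OR "),
                      character(1))
  ord <- order(-key, -pool$recall, pool$fallout, tie_label)
  pool[ord[1L], , drop = FALSE]
}
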