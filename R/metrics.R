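#' The 2x2 retrieval contingency table
#'
#' Cells follow the usual filter-evaluation layout: `a` relevant documents
#' retrieved, `b` nonrelevant retrieved, `c` relevant missed, `d`
#' nonrelevant missed, so `a + c` is the gold-standard size and `b + d`
#' the nonrelevant count.
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @return an object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0))
    stop("contingency cells must be nonnegative counts", call. = FALSE)
  structure(as.list(cells), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("retrieved", "missed"),
                              c("relevant", "nonrelevant")))
  print(m)
  invisible(x)
}

#' Cross a retrieval set with the gold standard
#'
#' @param corpus a `labeled_corpus`.
#' @param retrieved character vector of retrieved doc_ids (must all exist
#'   in the corpus).
#' @return a [contingency_table()].
#' @export
build_contingency <- function(corpus, retrieved) {
  stopifnot(inherits(corpus, "labeled_corpus"))
  retrieved <- unique(as.character(retrieved))
  unknown <- setdiff(retrieved, corpus$corpus$ids)
  if (length(unknown))
    stop("retrieved set contains IDs absent from the corpus: ",
         paste(utils::head(unknown, 10), collapse = ", "), call. = FALSE)
  rel <- corpus$relevant_ids
  a <- length(intersect(retrieved, rel))
  b <- length(retrieved) - a
  c <- length(rel) - a
  d <- length(corpus$corpus$ids) - a - b - c
  contingency_table(a, b, c, d)
}

#' Retrieval performance measures of a filter
#'
#' Computes recall `A/(A+C)`, precision `A/(A+B)`, F-measure
#' `2PR/(P+R)`, fallout `B/(B+D)` and the number needed to read
#' `1/precision`. Recall, precision and fallout are reported in percent;
#' the F-measure is computed on that same percent scale; NNR is in
#' articles per relevant article. When nothing is retrieved, precision is
#' undefined (`NA`, not 0) and NNR is infinite.
#'
#' @param table a [contingency_table()]; recall requires `a + c > 0`.
#' @return an object of class `metrics_report` with elements `recall`,
#'   `precision`, `f_measure`, `fallout`, `nnr` (all full precision) and
#'   the source `table`. Use [rounded_metrics()] for report-style rounding.
#' @examples
#' compute_metrics(contingency_table(a = 57, b = 150, c = 3, d = 1000))
#' @export
compute_metrics <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  if (a + c == 0)
    stop("recall undefined: no relevant documents (a + c = 0)",
         call. = FALSE)
  recall <- 100 * a / (a + c)
  precision <- if (a + b == 0) NA_real_ else 100 * a / (a + b)
  fallout <- if (b + d == 0) NA_real_ else 100 * b / (b + d)
  structure(list(recall = recall, precision = precision,
                 f_measure = f_measure(recall, precision),
                 fallout = fallout,
                 nnr = number_needed_to_read(precision),
                 table = table),
            class = "metrics_report")
}

#' F-measure and NNR from percent-scale recall and precision
#'
#' Convenience forms of the report formulas for when only the (recall,
#' precision) pair is at hand, e.g. re-deriving published table cells.
#' Both arguments are percentages; the F-measure comes back on the same
#' percent scale and NNR in articles per relevant article.
#'
#' @param recall,precision percentages in `[0, 100]`.
#' @return `f_measure`: `2PR/(P+R)` (0 when both are 0, `NA` if precision
#'   is `NA`); `number_needed_to_read`: `100/precision` (`Inf` at 0).
#' @examples
#' f_measure(98, 0.13)            # 0.26 after rounding to 2 d.p.
#' number_needed_to_read(22)      # 4.5 articles per relevant article
#' @export
f_measure <- function(recall, precision) {
  ifelse(is.na(precision), NA_real_,
         ifelse(precision + recall == 0, 0,
                2 * precision * recall / (precision + recall)))
}

#' @rdname f_measure
#' @export
number_needed_to_read <- function(precision) {
  ifelse(is.na(precision) | precision == 0, Inf, 100 / precision)
}

#' @export
print.metrics_report <- function(x, ...) {
  r <- rounded_metrics(x)
  cat(sprintf("recall %s%%  precision %s%%  F %s  fallout %s%%  NNR %s\n",
              r$recall, r$precision, r$f_measure,
              round(x$fallout, 2), r$nnr))
  invisible(x)
}

#' Report-style rounding of a metrics report
#'
#' Whole percent for recall; two decimals for precision, F-measure and
#' fallout; NNR to two significant figures up to 10 and to the nearest
#' integer above. Raw values stay available on the original report.
#'
#' @param report a `metrics_report`.
#' @return a list with the rounded `recall`, `precision`, `f_measure`,
#'   `fallout` and `nnr`.
#' @export
rounded_metrics <- function(report) {
  stopifnot(inherits(report, "metrics_report"))
  nnr <- report$nnr
  list(recall = round(report$recall),
       precision = round(report$precision, 2),
       f_measure = round(report$f_measure, 2),
       fallout = round(report$fallout, 2),
       nnr = if (is.infinite(nnr)) Inf else
         if (nnr <= 10) signif(nnr, 2) else round(nnr))
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(recall = x$recall, precision = x$precision,
             f_measure = x$f_measure, fallout = x$fallout, nnr = x$nnr)
}

#' Prevalence-balanced misclassification costs
#'
#' The default cost pair for [weighted_error_rate()] and tree growth:
#' `cost_fn = 1/prevalence`, `cost_fp = 1/(1 - prevalence)`. Under these
#' costs the weighted error rate reduces to the mean of the miss rate and
#' the fallout (as fractions), so the rare relevant class is not swamped
#' by the nonrelevant bulk.
#'
#' @param prevalence fraction of relevant documents, in (0, 1).
#' @return list with `cost_fn` and `cost_fp`.
#' @export
balanced_costs <- function(prevalence) {
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly between 0 and 1", call. = FALSE)
  list(cost_fn = 1 / prevalence, cost_fp = 1 / (1 - prevalence))
}

#' Cost-weighted misclassification rate of a retrieval split
#'
#' `(cost_fn * c + cost_fp * b) / (cost_fn * (a + c) + cost_fp * (b + d))`:
#' the cost incurred by the filter's errors over the cost of
#' misclassifying everything. Zero iff the filter classifies perfectly;
#' invariant under joint rescaling of both costs.
#'
#' @param table a [contingency_table()].
#' @param cost_fn,cost_fp strictly positive costs of a false negative
#'   (missed relevant article) and a false positive (retrieved
#'   nonrelevant article).
#' @return a number in `[0, 1]`.
#' @export
weighted_error_rate <- function(table, cost_fn, cost_fp) {
  stopifnot(inherits(table, "contingency_table"))
  if (!is.numeric(cost_fn) || !is.numeric(cost_fp) ||
      cost_fn <= 0 || cost_fp <= 0)
    stop("misclassification costs must be strictly positive", call. = FALSE)
  num <- cost_fn * table$c + cost_fp * table$b
  den <- cost_fn * (table$a + table$c) + cost_fp * (table$b + table$d)
  if (den == 0) return(0)
  num / den
}

#' Significance of the association captured by a split
#'
#' Pearson chi-square test of independence on the 2x2 retrieved-by-relevant
#' table, one degree of freedom, without continuity correction. When any
#' expected cell count falls below 5 the two-sided exact
#' (hypergeometric) test is used instead. A zero margin means no
#' association is testable and returns p = 1.
#'
#' @param table a [contingency_table()].
#' @return the p-value in `[0, 1]`.
#' @export
split_significance <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  m <- matrix(c(table$a, table$b, table$c, table$d), 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5))
    stats::fisher.test(m)$p.value
  else
    suppressWarnings(stats::chisq.test(m, correct = FALSE))$p.value
}
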