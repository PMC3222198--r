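#' Configuration for recursive-partitioning filter induction
#'
#' @param alpha significance level a split's 2x2 association must reach
#'   (chi-square / exact test); growth along a branch stops once the best
#'   available split's p-value exceeds `alpha`. Default 0.05.
#' @param recall_floor minimum whole-tree recall (percent) the final
#'   filter must preserve; leaf classification is forced toward
#'   "retrieve" until the floor is met. Default 99.
#' @param cost_fn,cost_fp misclassification costs; `NULL` (default) uses
#'   [balanced_costs()] at the training corpus prevalence, so the rare
#'   relevant class is not swamped.
#' @param max_depth safety bound on tree depth (overfitting guard).
#'   Default 10.
#' @return an object of class `rp_config`.
#' @export
rp_config <- function(alpha = 0.05, recall_floor = 99, cost_fn = NULL,
                      cost_fp = NULL, max_depth = 10L) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly in (0, 1)", call. = FALSE)
  if (!is.numeric(recall_floor) || recall_floor < 0 || recall_floor > 100)
    stop("recall_floor must lie in [0, 100]", call. = FALSE)
  if (!is.null(cost_fn) && cost_fn <= 0) stop("cost_fn must be positive",
                                              call. = FALSE)
  if (!is.null(cost_fp) && cost_fp <= 0) stop("cost_fp must be positive",
                                              call. = FALSE)
  structure(list(alpha = alpha, recall_floor = recall_floor,
                 cost_fn = cost_fn, cost_fp = cost_fp,
                 max_depth = as.integer(max_depth)),
            class = "rp_config")
}

resolve_costs <- function(config, corpus) {
  if (is.null(config$cost_fn) || is.null(config$cost_fp)) {
    bc <- balanced_costs(prevalence(corpus))
    list(cost_fn = config$cost_fn %||% bc$cost_fn,
         cost_fp = config$cost_fp %||% bc$cost_fp)
  } else {
    list(cost_fn = config$cost_fn, cost_fp = config$cost_fp)
  }
}

#' Choose the best split for a node's document subset
#'
#' Evaluates every available candidate on the subset and returns the one
#' with the lowest cost-weighted error rate, with its split-significance
#' p-value. Ties break deterministically: higher recall on the subset
#' first, then lower fallout, then the smaller label. Returns `NULL` when
#' the best split fails the significance threshold.
#'
#' @param corpus a `labeled_corpus`.
#' @param candidates a `candidate_set` scored on this corpus.
#' @param config an [rp_config()].
#' @param doc_ids optional character vector restricting the node to a
#'   document subset (default: the whole corpus).
#' @return a list with `term` (label), `weighted_error`, `p_value`,
#'   `table` (the 2x2 split table on the subset) and `child_tables`
#'   (tables the present/absent children would induce with the leaf class
#'   each would take), or `NULL` if no split is significant at `alpha`.
#' @export
choose_split <- function(corpus, candidates, config = rp_config(),
                         doc_ids = NULL) {
  stopifnot(inherits(corpus, "labeled_corpus"),
            inherits(candidates, "candidate_set"))
  if (!length(candidates)) stop("empty candidate list", call. = FALSE)
  costs <- resolve_costs(config, corpus)
  rel <- relevance_vector(corpus)
  idx <- if (is.null(doc_ids)) seq_along(rel) else
    match(doc_ids, corpus$corpus$ids)
  if (anyNA(idx)) stop("doc_ids contains unknown IDs", call. = FALSE)
  if (!length(idx)) stop("node document subset is empty", call. = FALSE)
  matches <- vapply(candidates, `[[`, logical(length(rel)), "matches")
  if (is.null(dim(matches))) matches <- matrix(matches, nrow = length(rel))
  labels <- vapply(candidates, `[[`, character(1), "label")
  best <- best_split_at(rel[idx],
                        matches[idx, , drop = FALSE],
                        seq_along(candidates), labels,
                        costs$cost_fn, costs$cost_fp)
  if (is.null(best) || best$p_value > config$alpha) return(NULL)
  best
}

# core split search over a logical label vector and a match matrix slice
best_split_at <- function(rel, m, avail, labels, cost_fn, cost_fp) {
  if (!length(avail)) return(NULL)
  stats <- lapply(avail, function(j) {
    pres <- m[, j]
    tab <- contingency_table(a = sum(pres & rel), b = sum(pres & !rel),
                             c = sum(!pres & rel), d = sum(!pres & !rel))
    err <- weighted_error_rate(tab, cost_fn, cost_fp)
    nrel <- tab$a + tab$c
    nirr <- tab$b + tab$d
    list(j = j, table = tab, err = err,
         recall = if (nrel > 0) tab$a / nrel else 0,
         fallout = if (nirr > 0) tab$b / nirr else 0)
  })
  err <- vapply(stats, `[[`, numeric(1), "err")
  rec <- vapply(stats, `[[`, numeric(1), "recall")
  fo <- vapply(stats, `[[`, numeric(1), "fallout")
  lab <- labels[avail]
  pick <- order(err, -rec, fo, lab)[1L]
  s <- stats[[pick]]
  tab <- s$table
  list(term = labels[s$j], term_index = s$j, weighted_error = s$err,
       p_value = split_significance(tab), table = tab,
       child_tables = list(
         present = contingency_table(tab$a, tab$b, 0, 0),
         absent = contingency_table(0, 0, tab$c, tab$d)))
}

#' Grow a multi-term Boolean filter by recursive partitioning
#'
#' Greedy tree induction over Boolean term-filters as predictors: each
#' node splits its documents on the candidate with the lowest
#' cost-weighted error rate; a split is accepted only when its 2x2
#' association is significant at `alpha` *and* it strictly lowers the
#' tree's total weighted misclassification cost. A term used on a path is
#' removed from that path's slate but stays available to sibling
#' subtrees. Leaves are then classified to minimize cost (ties retrieve,
#' favoring recall), and classification is forced toward "retrieve" — in
#' cheapest-first order — until whole-tree recall reaches `recall_floor`.
#'
#' @param corpus a `labeled_corpus` (the training database).
#' @param candidates a `candidate_set` from [candidate_terms()],
#'   typically pre-screened with [screen_terms()] in `"or"` mode.
#' @param config an [rp_config()].
#' @return an object of class `rp_tree`; see [tree_to_boolean()] to
#'   convert it to a query, [rp_tree_retrieve()] to apply it.
#' @export
grow_rp_tree <- function(corpus, candidates, config = rp_config()) {
  stopifnot(inherits(corpus, "labeled_corpus"),
            inherits(candidates, "candidate_set"))
  if (!length(candidates)) stop("empty candidate list", call. = FALSE)
  costs <- resolve_costs(config, corpus)
  rel <- relevance_vector(corpus)
  ids <- corpus$corpus$ids
  matches <- vapply(candidates, `[[`, logical(length(rel)), "matches")
  if (is.null(dim(matches))) matches <- matrix(matches, nrow = length(rel))
  labels <- vapply(candidates, `[[`, character(1), "label")
  cfn <- costs$cost_fn
  cfp <- costs$cost_fp

  build <- function(idx, avail, depth) {
    nrel <- sum(rel[idx])
    nirr <- length(idx) - nrel
    make_leaf <- function() structure(
      list(leaf = TRUE, doc_ids = ids[idx], n_rel = nrel, n_irrel = nirr,
           class = NA_character_), class = "rp_node")
    if (depth >= config$max_depth || !length(avail) ||
        nrel == 0L || nirr == 0L)
      return(make_leaf())
    best <- best_split_at(rel[idx], matches[idx, , drop = FALSE],
                          avail, labels, cfn, cfp)
    # stopping rule: the two tables created by the split are no longer
    # significantly different
    if (is.null(best) || best$p_value > config$alpha) return(make_leaf())
    pres <- matches[idx, best$term_index]
    rest <- setdiff(avail, best$term_index)
    structure(
      list(leaf = FALSE, term = best$term,
           split_node = candidates[[best$term_index]]$node,
           weighted_error = best$weighted_error, p_value = best$p_value,
           table = best$table, doc_ids = ids[idx], n_rel = nrel,
           n_irrel = nirr,
           present = build(idx[pres], rest, depth + 1L),
           absent = build(idx[!pres], rest, depth + 1L)),
      class = "rp_node")
  }

  root <- build(seq_along(rel), seq_along(candidates), 0L)
  root <- classify_leaves(root, cfn, cfp)
  root <- enforce_recall_floor(root, sum(rel), config$recall_floor,
                               cfn, cfp)
  root <- prune_same_class(root)
  structure(list(root = root, cost_fn = cfn, cost_fp = cfp,
                 config = config, n_docs = length(rel),
                 n_rel = sum(rel), candidate_labels = labels),
            class = "rp_tree")
}

classify_leaves <- function(node, cfn, cfp) {
  if (node$leaf) {
    # retrieving costs cfp per nonrelevant doc; discarding cfn per
    # relevant doc; ties retrieve (recall-first objective); an empty
    # leaf is inert and stays out of the Boolean conversion
    node$class <- if (node$n_rel + node$n_irrel == 0L) "discard"
      else if (cfn * node$n_rel >= cfp * node$n_irrel) "retrieve"
      else "discard"
    return(node)
  }
  node$present <- classify_leaves(node$present, cfn, cfp)
  node$absent <- classify_leaves(node$absent, cfn, cfp)
  node
}

collect_leaves <- function(node, path = integer()) {
  if (node$leaf) return(list(node))
  c(collect_leaves(node$present), collect_leaves(node$absent))
}

enforce_recall_floor <- function(root, total_rel, floor, cfn, cfp) {
  repeat {
    leaves <- collect_leaves(root)
    got <- sum(vapply(leaves, function(l)
      if (l$class == "retrieve") l$n_rel else 0L, numeric(1)))
    if (100 * got / total_rel >= floor) return(root)
    # flip the discard leaf recovering recall at least added cost
    cand <- Filter(function(l) l$class == "discard" && l$n_rel > 0, leaves)
    if (!length(cand)) return(root) # unreachable: flipping all gives 100
    ratio <- vapply(cand, function(l) cfp * l$n_irrel / (cfn * l$n_rel),
                    numeric(1))
    target <- cand[[order(ratio)[1L]]]
    root <- flip_leaf(root, target$doc_ids[1L])
  }
}

# collapse subtrees whose leaves all ended with the same class: such a
# split separates nothing after classification, so every retained split
# genuinely divides retrieve- from discard-regions
prune_same_class <- function(node) {
  if (node$leaf) return(node)
  node$present <- prune_same_class(node$present)
  node$absent <- prune_same_class(node$absent)
  if (node$present$leaf && node$absent$leaf &&
      identical(node$present$class, node$absent$class)) {
    return(structure(
      list(leaf = TRUE, doc_ids = node$doc_ids, n_rel = node$n_rel,
           n_irrel = node$n_irrel, class = node$present$class),
      class = "rp_node"))
  }
  node
}

flip_leaf <- function(node, marker_id) {
  if (node$leaf) {
    if (marker_id %in% node$doc_ids) node$class <- "retrieve"
    return(node)
  }
  node$present <- flip_leaf(node$present, marker_id)
  node$absent <- flip_leaf(node$absent, marker_id)
  node
}

#' Apply a grown tree to a corpus
#'
#' Routes every document down the tree (re-evaluating each split's query,
#' so fresh corpora work too) and returns the documents landing in
#' retrieve-leaves.
#'
#' @param tree an `rp_tree`.
#' @param corpus a `bib_corpus` or `labeled_corpus`.
#' @param hierarchy optional MeSH hierarchy.
#' @return character vector of retrieved doc_ids.
#' @export
rp_tree_retrieve <- function(tree, corpus, hierarchy = NULL) {
  stopifnot(inherits(tree, "rp_tree"))
  if (inherits(corpus, "labeled_corpus")) corpus <- corpus$corpus
  n <- length(corpus$docs)
  out <- logical(n)
  walk <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) {
      if (identical(node$class, "retrieve")) out[idx] <<- TRUE
      return()
    }
    m <- query_matches(corpus, node$split_node, hierarchy)[idx]
    walk(node$present, idx[m])
    walk(node$absent, idx[!m])
  }
  walk(tree$root, seq_len(n))
  corpus$ids[out]
}

#' Convert a grown tree to a Boolean filter
#'
#' Emits the disjunction, over retrieve-leaves, of each root-to-leaf
#' path's conditions (the split term on a present-edge; its set-difference
#' `NOT` on an absent-edge), factored through the tree structure so shared
#' prefixes are emitted once. The result is extensionally equivalent to
#' the tree on any corpus; syntactic minimality is best-effort (e.g.
#' `T OR (X NOT T)` simplifies to `T OR X`).
#'
#' @param tree an `rp_tree` with classified leaves.
#' @return a `query_node`; use [deparse_query()] for the filter string.
#' @export
tree_to_boolean <- function(tree) {
  stopifnot(inherits(tree, "rp_tree"))
  res <- node_to_boolean(tree$root)
  if (is.null(res))
    stop("tree has no retrieve-leaf: the induced filter is empty",
         call. = FALSE)
  if (identical(res, "ALL"))
    stop("tree retrieves every document: not expressible as a filter",
         call. = FALSE)
  res
}

node_to_boolean <- function(node) {
  if (node$leaf)
    return(if (identical(node$class, "retrieve")) "ALL" else NULL)
  p <- node_to_boolean(node$present)
  a <- node_to_boolean(node$absent)
  t <- node$split_node
  if (identical(p, "ALL") && identical(a, "ALL")) return("ALL")
  if (is.null(p) && is.null(a)) return(NULL)
  if (identical(a, "ALL")) {
    # the absent side retrieves everything: the filter would need an
    # unrestricted complement (NOT with no left operand), which the
    # dialect cannot express
    stop("tree requires unrestricted negation (absent-branch retrieves ",
         "all documents); cannot be expressed in the query dialect",
         call. = FALSE)
  }
  if (identical(p, "ALL")) {
    # T u (A \ T) = T u A
    if (is.null(a)) return(t)
    return(bool_node("OR", t, a))
  }
  part_p <- if (is.null(p)) NULL else bool_node("AND", t, p)
  part_a <- if (is.null(a)) NULL else bool_node("NOT", a, t)
  if (is.null(part_p)) return(part_a)
  if (is.null(part_a)) return(part_p)
  bool_node("OR", part_p, part_a)
}

#' @export
print.rp_tree <- function(x, ...) {
  cat(sprintf("<rp_tree> %d documents (%d relevant), costs fn=%.4g fp=%.4g\n",
              x$n_docs, x$n_rel, x$cost_fn, x$cost_fp))
  cat(format_rp_node(x$root), sep = "\n")
  invisible(x)
}

format_rp_node <- function(node, indent = "") {
  if (node$leaf) {
    return(sprintf("%s<%s> %d relevant / %d nonrelevant", indent,
                   node$class, node$n_rel, node$n_irrel))
  }
  c(sprintf("%ssplit: %s (weighted error %.4g, p = %.3g)", indent,
            node$term, node$weighted_error, node$p_value),
    sprintf("%s  present:", indent),
    format_rp_node(node$present, paste0(indent, "    ")),
    sprintf("%s  absent:", indent),
    format_rp_node(node$absent, paste0(indent, "    ")))
}

#' Serialize a grown tree to plain data
#'
#' @param tree an `rp_tree`.
#' @return a nested list (JSON-ready: see `jsonlite::toJSON`) with split
#'   terms, per-node counts, p-values and leaf classes.
#' @export
rp_tree_to_list <- function(tree) {
  stopifnot(inherits(tree, "rp_tree"))
  strip <- function(node) {
    if (node$leaf)
      return(list(leaf = TRUE, class = node$class,
                  n_rel = node$n_rel, n_irrel = node$n_irrel))
    list(leaf = FALSE, term = node$term,
         weighted_error = node$weighted_error, p_value = node$p_value,
         n_rel = node$n_rel, n_irrel = node$n_irrel,
         present = strip(node$present), absent = strip(node$absent))
  }
  list(n_docs = tree$n_docs, n_rel = tree$n_rel,
       cost_fn = tree$cost_fn, cost_fp = tree$cost_fp,
       root = strip(tree$root))
}
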