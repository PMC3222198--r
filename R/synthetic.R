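#' Configuration for the synthetic-corpus generator
#'
#' Describes a labeled corpus to simulate: size, gold-standard prevalence,
#' a vocabulary of single-token terms with class-conditional occurrence
#' probabilities and a target field each, and optionally a planted Boolean
#' rule that determines the label. The generator emulates the structure of
#' a hand-labeled bibliographic database with a very rare relevant class;
#' it is the package's stand-in for training/testing databases that cannot
#' be redistributed.
#'
#' @param n_docs number of documents (>= 1).
#' @param prevalence fraction of relevant documents in (0, 1); ignored
#'   when `planted_rule` is given (the rule and the background rates then
#'   determine prevalence).
#' @param vocabulary data frame with columns `term` (single alphanumeric
#'   token), `field` (one of `"title"`, `"abstract"`, `"mesh"`, `"pt"`),
#'   `p_relevant` (occurrence probability given relevant) and
#'   `p_background` (occurrence probability given nonrelevant). With a
#'   planted rule, `p_background` is the marginal occurrence rate for all
#'   documents and `p_relevant` is unused.
#' @param planted_rule optional query string over vocabulary terms; the
#'   label is the rule's evaluation, XOR noise.
#' @param label_noise probability of flipping a rule-determined label.
#' @param seed integer RNG seed; identical configs generate byte-identical
#'   corpora.
#' @return an object of class `synthetic_config`.
#' @seealso [generate_synthetic_corpus()]
#' @export
synthetic_config <- function(n_docs, prevalence = 0.001, vocabulary,
                             planted_rule = NULL, label_noise = 0,
                             seed = 1L) {
  if (!is.numeric(n_docs) || n_docs < 1)
    stop("n_docs must be a positive integer", call. = FALSE)
  if (!is.numeric(prevalence) || prevalence < 0 || prevalence > 1)
    stop("prevalence must lie in [0, 1]", call. = FALSE)
  if (!is.data.frame(vocabulary) ||
      !all(c("term", "field", "p_relevant", "p_background") %in%
           names(vocabulary)))
    stop("vocabulary needs columns term, field, p_relevant, p_background",
         call. = FALSE)
  if (any(!vocabulary$field %in% c("title", "abstract", "mesh", "pt")))
    stop("vocabulary field must be title, abstract, mesh or pt",
         call. = FALSE)
  probs <- c(vocabulary$p_relevant, vocabulary$p_background, label_noise)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (anyDuplicated(vocabulary$term))
    stop("vocabulary terms must be unique", call. = FALSE)
  rule_node <- NULL
  if (!is.null(planted_rule)) {
    rule_node <- if (inherits(planted_rule, "query_node")) planted_rule
                 else parse_query(planted_rule)
    rule_terms <- tolower(query_leaf_terms(rule_node))
    extra <- setdiff(rule_terms, tolower(vocabulary$term))
    if (length(extra))
      stop("planted_rule references terms outside the vocabulary: ",
           paste(extra, collapse = ", "), call. = FALSE)
  }
  structure(list(n_docs = as.integer(n_docs), prevalence = prevalence,
                 vocabulary = vocabulary, planted_rule = rule_node,
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "synthetic_config")
}

query_leaf_terms <- function(node) {
  if (node$kind == "term") return(node$term)
  c(query_leaf_terms(node$lhs), query_leaf_terms(node$rhs))
}

#' Generate a seeded synthetic labeled corpus
#'
#' Without a planted rule, labels are drawn independently at the
#' configured prevalence and each vocabulary term occurs with its
#' class-conditional probability. With a planted rule, every term occurs
#' at its background rate and the label is the rule evaluated on the
#' generated document (flipped with probability `label_noise`). Terms are
#' placed as single tokens into the configured field: appended to the
#' title, to the abstract, as a MeSH heading, or as a publication type.
#'
#' @param config a [synthetic_config()].
#' @return a [labeled_corpus()] carrying a `ground_truth` attribute (the
#'   planted rule, the per-document true labels, and the config).
#' @examples
#' vocab <- data.frame(term = c("alpha", "beta"), field = "abstract",
#'                     p_relevant = c(0.9, 0.1), p_background = c(0.05, 0.1))
#' generate_synthetic_corpus(synthetic_config(500, 0.05, vocab, seed = 7))
#' @export
generate_synthetic_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_docs
  vocab <- config$vocabulary
  m <- nrow(vocab)
  set.seed(config$seed)

  if (is.null(config$planted_rule)) {
    if (config$prevalence <= 0 || config$prevalence >= 1)
      stop("degenerate corpus: prevalence must lie strictly in (0, 1)",
           call. = FALSE)
    rel <- stats::runif(n) < config$prevalence
    occ <- matrix(FALSE, n, m)
    for (j in seq_len(m)) {
      p <- ifelse(rel, vocab$p_relevant[j], vocab$p_background[j])
      occ[, j] <- stats::runif(n) < p
    }
  } else {
    occ <- matrix(FALSE, n, m)
    for (j in seq_len(m))
      occ[, j] <- stats::runif(n) < vocab$p_background[j]
    rel <- NULL # assigned below, once documents exist
  }

  ids <- sprintf("SYN%06d", seq_len(n))
  docs <- lapply(seq_len(n), function(i) {
    present <- which(occ[i, ])
    fields <- vocab$field[present]
    terms <- vocab$term[present]
    title <- paste(c(paste("synthetic record", i),
                     terms[fields == "title"]), collapse = " ")
    abstract <- paste(terms[fields == "abstract"], collapse = " ")
    mesh <- lapply(terms[fields == "mesh"], function(t)
      list(heading = t, subheadings = character(), major = FALSE))
    document(doc_id = ids[i], title = title, abstract = abstract,
             mesh = mesh, pub_types = terms[fields == "pt"])
  })
  corpus <- bib_corpus(docs)

  if (!is.null(config$planted_rule)) {
    rel <- query_matches(corpus, config$planted_rule)
    if (config$label_noise > 0)
      rel <- xor(rel, stats::runif(n) < config$label_noise)
  }
  if (!any(rel) || all(rel))
    stop("degenerate corpus: generated labels are all identical ",
         "(prevalence effectively 0 or 1)", call. = FALSE)

  out <- labeled_corpus(corpus, ids[rel])
  attr(out, "ground_truth") <- list(
    planted_rule = if (!is.null(config$planted_rule))
      deparse_query(config$planted_rule),
    labels = rel, config = config)
  out
}
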