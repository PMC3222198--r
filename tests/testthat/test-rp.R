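# handcrafted tree nodes for conversion tests
rp_leaf <- function(class) {
  structure(list(leaf = TRUE, class = class, doc_ids = character(),
                 n_rel = 0L, n_irrel = 0L), class = "rp_node")
}
rp_internal <- function(term, present, absent) {
  structure(list(leaf = FALSE, term = term,
                 split_node = parse_query(term),
                 present = present, absent = absent), class = "rp_node")
}
as_rp_tree <- function(root) {
  structure(list(root = root, cost_fn = 1, cost_fp = 1, n_docs = NA,
                 n_rel = NA, config = rp_config()), class = "rp_tree")
}

test_that("choose_split picks the lowest weighted error, gated by alpha", {
  # alpha separates the classes nearly perfectly: it must win with a
  # tiny p-value
  vocab <- test_vocabulary()
  vocab$p_relevant[1] <- 1; vocab$p_background[1] <- 0
  lc <- generate_synthetic_corpus(synthetic_config(400, 0.1, vocab,
                                                   seed = 4))
  cands <- candidate_terms(
    c("alpha[tw]", "beta[tw]", "noise1[tw]"), lc)
  s <- choose_split(lc, cands)
  expect_equal(s$term, "alpha[tw]")
  expect_equal(s$weighted_error, 0)
  expect_lt(s$p_value, 1e-6)
  # uninformative candidates (zero-margin splits) give p = 1 -> no split
  none <- choose_split(lc, candidate_terms(
    c("synthetic[tw]", "zzznothing[tw]"), lc))
  expect_null(none)
  expect_error(choose_split(lc, structure(list(), class = "candidate_set")),
               "empty candidate")
})

test_that("choose_split agrees with exhaustive per-candidate scoring", {
  for (seed in 1:6) {
    lc <- random_corpus(n = 300, prevalence = 0.12, seed = seed)
    labels <- c("alpha[tw]", "beta[tw]", "gamma[tw]", "noise1[tw]",
                "noise2[tw]")
    cands <- candidate_terms(labels, lc)
    costs <- balanced_costs(prevalence(lc))
    rel <- corpus_ids(lc) %in% lc$relevant_ids
    errs <- vapply(cands, function(cd) {
      weighted_error_rate(
        contingency_table(sum(cd$matches & rel), sum(cd$matches & !rel),
                          sum(!cd$matches & rel), sum(!cd$matches & !rel)),
        costs$cost_fn, costs$cost_fp)
    }, numeric(1))
    s <- choose_split(lc, cands)
    if (!is.null(s)) {
      expect_equal(s$weighted_error, min(errs))
      expect_true(s$term %in% labels[errs == min(errs)])
    }
  }
})

test_that("a corpus labeled by a single term grows a depth-1 tree", {
  vocab <- data.frame(term = c("marker", "noisea", "noiseb"),
                      field = "abstract", p_relevant = 0,
                      p_background = c(0.15, 0.3, 0.4))
  lc <- generate_synthetic_corpus(
    synthetic_config(1000, vocabulary = vocab, planted_rule = "marker[tw]",
                     seed = 6))
  cands <- candidate_terms(c("marker[tw]", "noisea[tw]", "noiseb[tw]"), lc)
  tree <- grow_rp_tree(lc, cands)
  expect_false(tree$root$leaf)
  expect_equal(tree$root$term, "marker[tw]")
  expect_true(tree$root$present$leaf)
  expect_true(tree$root$absent$leaf)
  expect_equal(tree$root$present$class, "retrieve")
  expect_equal(tree$root$absent$class, "discard")
  expect_equal(deparse_query(tree_to_boolean(tree)), "marker[tw]")
  # determinism: identical corpus and config give identical trees
  tree2 <- grow_rp_tree(lc, cands)
  expect_identical(rp_tree_to_list(tree2), rp_tree_to_list(tree))
})

test_that("a noiseless planted AND/OR rule is recovered exactly", {
  vocab <- data.frame(
    term = c("t1", "t2", "t3", paste0("d", 1:10)), field = "abstract",
    p_relevant = 0,
    p_background = c(0.1, 0.1, 0.01,
                     seq(0.05, 0.3, length.out = 10)))
  cfg <- synthetic_config(4000, vocabulary = vocab,
                          planted_rule = "(t1[tw] AND t2[tw]) OR t3[tw]",
                          seed = 12)
  lc <- generate_synthetic_corpus(cfg)
  cands <- candidate_terms(paste0(vocab$term, "[tw]"), lc)
  tree <- grow_rp_tree(lc, cands)
  filt <- tree_to_boolean(tree)
  m <- compute_metrics(build_contingency(lc, retrieve(lc, filt)))
  expect_equal(m$recall, 100)
  expect_equal(m$precision, 100)
})

test_that("tree and its Boolean conversion retrieve identical sets", {
  lc <- random_corpus(n = 1200, prevalence = 0.05, seed = 19)
  cands <- candidate_terms(
    c("alpha[tw]", "beta[tw]", "gamma[tw]", "noise1[tw]", "noise2[tw]"),
    lc)
  tree <- grow_rp_tree(lc, cands, rp_config(recall_floor = 90))
  filt <- tree_to_boolean(tree)
  expect_setequal(retrieve(lc, filt), rp_tree_retrieve(tree, lc))
  # and on a fresh corpus from a different seed
  fresh <- random_corpus(n = 800, prevalence = 0.05, seed = 91)
  expect_setequal(retrieve(fresh, filt), rp_tree_retrieve(tree, fresh))
})

test_that("whole-tree recall respects the configured floor", {
  for (seed in c(23, 24, 25)) {
    lc <- random_corpus(n = 1000, prevalence = 0.05, seed = seed)
    cands <- candidate_terms(
      c("alpha[tw]", "beta[tw]", "gamma[tw]", "noise1[tw]"), lc)
    for (floor in c(50, 90, 99)) {
      tree <- grow_rp_tree(lc, cands, rp_config(recall_floor = floor))
      got <- rp_tree_retrieve(tree, lc)
      m <- compute_metrics(build_contingency(lc, got))
      expect_gte(m$recall, floor)
    }
  }
})

test_that("conversion factors shared prefixes and drops redundant NOTs", {
  # a tree splitting first on a MeSH term, then diagnosis and truncated
  # text words, mirrors the canonical multi-term filter shape
  root <- rp_internal(
    "\"sensitivity and specificity\"[MeSH]",
    rp_leaf("retrieve"),
    rp_internal(
      "Diagnosis[tw]",
      rp_internal("specific*[tw]", rp_leaf("retrieve"),
                  rp_internal("clinical*[tw]", rp_leaf("retrieve"),
                              rp_internal("exam*[tw]", rp_leaf("retrieve"),
                                          rp_leaf("discard")))),
      rp_leaf("discard")))
  tree <- as_rp_tree(root)
  filt <- tree_to_boolean(tree)
  published <- parse_query(paste0(
    "(Diagnosis[tw] AND (specific*[tw] OR clinical*[tw] OR exam*[tw])) ",
    "OR \"sensitivity and specificity\"[MeSH]"))
  # extensional equality with the published filter on arbitrary corpora
  set.seed(77)
  for (rep in 1:3) {
    docs <- lapply(1:60, function(i) {
      words <- c("diagnosis", "specificity", "clinical", "examination",
                 "unrelated", "finding")[runif(6) < 0.4]
      document(sprintf("r%d", i),
               title = paste(c("study", words), collapse = " "),
               mesh = if (runif(1) < 0.3)
                 list(list(heading = "Sensitivity and Specificity"))
               else list())
    })
    corp <- bib_corpus(docs)
    expect_setequal(retrieve(corp, filt), retrieve(corp, published))
    expect_setequal(rp_tree_retrieve(tree, corp), retrieve(corp, filt))
  }
  # degenerate trees cannot be converted
  expect_error(tree_to_boolean(as_rp_tree(rp_leaf("discard"))),
               "no retrieve-leaf")
  expect_error(
    tree_to_boolean(as_rp_tree(
      rp_internal("x[tw]", rp_leaf("discard"), rp_leaf("retrieve")))),
    "negation")
})
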