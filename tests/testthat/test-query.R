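rp_filter_string <- paste0(
  "(Diagnosis[tw] AND (specific*[tw] OR clinical*[tw] OR exam*[tw])) ",
  "OR \"sensitivity and specificity\"[MeSH]")

test_that("the multi-term filter string parses into the expected tree", {
  q <- parse_query(rp_filter_string)
  expect_equal(q$op, "OR")
  expect_equal(q$lhs$op, "AND")
  left_leaf <- q$lhs$lhs
  expect_equal(left_leaf$term, "Diagnosis")
  expect_equal(left_leaf$field, "tw")
  inner <- q$lhs$rhs # (specific* OR clinical*) OR exam*, left-associative
  expect_equal(inner$op, "OR")
  expect_equal(inner$rhs$term, "exam")
  expect_true(inner$rhs$truncated)
  expect_equal(inner$lhs$lhs$term, "specific")
  right_leaf <- q$rhs
  expect_equal(right_leaf$term, "sensitivity and specificity")
  expect_equal(right_leaf$field, "mesh")
})

test_that("field tags are case-insensitive with documented aliases", {
  expect_equal(parse_query("diagnosis[subheading]")$field, "sh")
  expect_equal(parse_query("diagnosis[SH]")$field, "sh")
  expect_equal(parse_query("Predictive value of tests[mesh]")$term,
               "Predictive value of tests")
  expect_equal(parse_query("Predictive value of tests[mesh]")$field, "mesh")
  expect_equal(parse_query("x[TIAB]")$field, "tiab")
  expect_equal(parse_query("x[Title]")$field, "ti")
  q <- parse_query("hypertension[MeSH:noexp]")
  expect_equal(q$field, "mesh")
  expect_true(q$noexp)
  # untagged terms default to text word
  expect_equal(parse_query("dyspnea")$field, "tw")
})

test_that("malformed queries fail with positioned parse errors", {
  expect_error(parse_query("a[tw] AND ("), "empty operand|unbalanced")
  expect_error(parse_query("a[tw] AND"), "empty operand")
  expect_error(parse_query("(a[tw] OR b[tw]"), "unbalanced parenthesis")
  expect_error(parse_query("\"unclosed phrase[tw]"), "unbalanced quote")
  expect_error(parse_query("x[nosuchtag]"), "unknown field tag")
  expect_error(parse_query("x[sh:noexp]"), "unknown field tag")
  expect_error(parse_query("NOT mri[tw]"), "no left operand")
  expect_error(parse_query("AND b"), "no left operand")
  expect_error(parse_query(""), "non-empty")
  expect_error(parse_query("a) b"), "unexpected")
})

test_that("re-serialization is semantically identical", {
  queries <- c(rp_filter_string,
               "diagnosis[subheading]",
               "tests[tw] OR physical[tw] NOT mri[ti]",
               "\"medical history taking\"[MeSH] AND exam*[TIAB]")
  corp <- tiny_corpus()
  for (q in queries) {
    node <- parse_query(q)
    reparsed <- parse_query(deparse_query(node))
    expect_equal(retrieve(corp, reparsed), retrieve(corp, node), info = q)
  }
})

test_that("leaf semantics match field scopes on a handcrafted corpus", {
  corp <- tiny_corpus()
  # [sh]: attached subheading names
  expect_setequal(retrieve(corp, "diagnosis[sh]"), c("d1", "d3", "d4"))
  # [ti] vs [TIAB] vs [tw] widening scopes
  expect_setequal(retrieve(corp, "specificity[ti]"), character())
  expect_setequal(retrieve(corp, "specificity[TIAB]"), "d1")
  expect_setequal(retrieve(corp, "imaging[ti]"), character())
  expect_setequal(retrieve(corp, "imaging[TIAB]"), "d2")
  # [tw] reaches MeSH heading and subheading names
  expect_setequal(retrieve(corp, "appendicitis[tw]"), "d3")
  expect_setequal(retrieve(corp, "surgery[tw]"), "d3")
  # [MeSH] is an exact heading-name match, not tokenized
  expect_setequal(retrieve(corp, "\"physical examination\"[MeSH]"), "d1")
  expect_setequal(retrieve(corp, "examination[MeSH]"), character())
  expect_setequal(retrieve(corp, "Medical history taking[MeSH]"), "d3")
  # [pt]: publication types
  expect_setequal(retrieve(corp, "\"journal article\"[pt]"),
                  c("d1", "d2", "d4"))
  # truncation is token-prefix matching
  expect_setequal(retrieve(corp, "exam*[tw]"), c("d1", "d4"))
  expect_setequal(retrieve(corp, "specific*[tw]"), c("d1", "d4"))
  # quoted phrases match consecutive tokens
  expect_setequal(retrieve(corp, "\"sensitivity and specificity\"[TIAB]"),
                  "d1")
  expect_setequal(retrieve(corp, "\"specificity and sensitivity\"[TIAB]"),
                  character())
  # matching is case-insensitive
  expect_setequal(retrieve(corp, "HEART[tw]"), retrieve(corp, "heart[tw]"))
})

test_that("MeSH explosion follows a supplied hierarchy and noexp blocks it", {
  corp <- tiny_corpus()
  hier <- read_mesh_hierarchy(text = c(
    "Heart Failure\tHeart Diseases",
    "Pneumonia\tRespiratory Tract Infections",
    "Heart Diseases\tCardiovascular Diseases"))
  expect_setequal(retrieve(corp, "\"heart diseases\"[MeSH]"), character())
  expect_setequal(retrieve(corp, "\"heart diseases\"[MeSH]", hier), "d1")
  # grandparent explodes transitively
  expect_setequal(retrieve(corp, "\"cardiovascular diseases\"[MeSH]", hier),
                  "d1")
  expect_setequal(retrieve(corp, "\"heart diseases\"[MeSH:noexp]", hier),
                  character())
  expect_setequal(mesh_descendants(hier, "Cardiovascular Diseases"),
                  c("heart diseases", "heart failure"))
})

test_that("boolean operators behave as set algebra on retrieval sets", {
  lc <- random_corpus(n = 300, seed = 21)
  A <- "alpha[tw]"; B <- "beta[tw]"; G <- "gamma[tw]"
  rA <- retrieve(lc, A); rB <- retrieve(lc, B); rG <- retrieve(lc, G)
  expect_setequal(retrieve(lc, paste(A, "OR", B)), union(rA, rB))
  expect_setequal(retrieve(lc, paste(A, "AND", B)), intersect(rA, rB))
  expect_setequal(retrieve(lc, paste(A, "NOT", B)), setdiff(rA, rB))
  # annihilation
  expect_length(retrieve(lc, paste(A, "NOT", A)), 0L)
  # commutativity / associativity
  expect_setequal(retrieve(lc, paste(B, "OR", A)),
                  retrieve(lc, paste(A, "OR", B)))
  expect_setequal(retrieve(lc, sprintf("(%s OR %s) OR %s", A, B, G)),
                  retrieve(lc, sprintf("%s OR (%s OR %s)", A, B, G)))
  # idempotence
  expect_setequal(retrieve(lc, paste(A, "OR", A)), rA)
  expect_setequal(retrieve(lc, paste(A, "AND", A)), rA)
  # De Morgan within the corpus: U \ (A u B) = (U \ A) n (U \ B)
  U <- corpus_ids(lc)
  expect_setequal(setdiff(U, union(rA, rB)),
                  intersect(setdiff(U, rA), setdiff(U, rB)))
  # precedence: NOT > AND > OR
  expect_setequal(retrieve(lc, sprintf("%s OR %s AND %s", A, B, G)),
                  union(rA, intersect(rB, rG)))
  expect_setequal(retrieve(lc, sprintf("%s AND %s NOT %s", A, B, G)),
                  intersect(rA, setdiff(rB, rG)))
})

test_that("corpus-level retrieval agrees with per-document evaluation", {
  lc <- random_corpus(n = 120, seed = 33)
  queries <- c("alpha[tw] AND beta[tw]",
               "(alpha[tw] OR gamma[tw]) NOT noise1[tw]",
               "beta[ti] OR gamma[tw]")
  for (q in queries)
    expect_setequal(retrieve(lc, q), brute_retrieve(lc, q))
  empty <- bib_corpus(list())
  expect_length(retrieve(empty, "alpha[tw]"), 0L)
})

test_that("OR never shrinks and AND never grows the retrieval set", {
  for (seed in 1:5) {
    lc <- random_corpus(n = 200, seed = seed)
    base <- retrieve(lc, "alpha[tw]")
    wider <- retrieve(lc, "alpha[tw] OR noise1[tw]")
    narrower <- retrieve(lc, "alpha[tw] AND noise1[tw]")
    expect_true(all(base %in% wider))
    expect_true(all(narrower %in% base))
  }
})
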