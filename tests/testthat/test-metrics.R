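test_that("contingency cells agree with direct per-document counting", {
  lc <- tiny_labeled()
  tab <- build_contingency(lc, c("d1", "d2"))
  expect_equal(unclass(tab)[c("a", "b", "c", "d")],
               list(a = 1, b = 1, c = 2, d = 1))
  # retrieved everything: nothing missed
  tab_all <- build_contingency(lc, corpus_ids(lc))
  expect_equal(tab_all$c, 0)
  expect_equal(tab_all$d, 0)
  expect_error(build_contingency(lc, c("d1", "zz")), "absent")

  # randomized recount oracle
  for (seed in 1:5) {
    lc2 <- random_corpus(n = 200, seed = seed)
    set.seed(seed + 100)
    ret <- sample(corpus_ids(lc2), 50)
    tab2 <- build_contingency(lc2, ret)
    rel <- corpus_ids(lc2) %in% lc2$relevant_ids
    got <- corpus_ids(lc2) %in% ret
    expect_equal(tab2$a, sum(rel & got))
    expect_equal(tab2$b, sum(!rel & got))
    expect_equal(tab2$c, sum(rel & !got))
    expect_equal(tab2$d, sum(!rel & !got))
  }
  # bookkeeping example: 188 relevant of which 4 missed
  lc3 <- random_corpus(n = 2000, prevalence = 0.15, seed = 8)
  rel_ids <- lc3$relevant_ids[1:188]
  lc3 <- labeled_corpus(lc3$corpus, rel_ids)
  tab3 <- build_contingency(lc3, rel_ids[1:184])
  expect_equal(tab3$a, 184)
  expect_equal(tab3$c, 4)
})

test_that("metric formulas reproduce published-style F and NNR cells", {
  # recall 98, precision 0.13 -> F 0.26 at 2 d.p.
  expect_equal(round(f_measure(98, 0.13), 2), 0.26)
  # recall 99, precision 22 -> F 36.0, NNR 4.5
  expect_equal(round(f_measure(99, 22), 1), 36.0)
  expect_equal(signif(number_needed_to_read(22), 2), 4.5)
  # full path through a table: a=57,c=3 gives recall 95; nnr = 1/precision
  m <- compute_metrics(contingency_table(57, 150, 3, 1000))
  expect_equal(m$recall, 95)
  expect_equal(m$nnr * m$precision / 100, 1)
  # forced by the formulas: a = c, b = d = 0
  m2 <- compute_metrics(contingency_table(5, 0, 5, 0))
  expect_equal(m2$recall, 50)
  expect_equal(m2$precision, 100)
  # nothing retrieved: precision undefined, NNR infinite
  m3 <- compute_metrics(contingency_table(0, 0, 10, 90))
  expect_true(is.na(m3$precision))
  expect_equal(m3$nnr, Inf)
  expect_error(compute_metrics(contingency_table(0, 5, 0, 5)),
               "recall undefined")
})

test_that("harmonic-mean bound and NNR identity hold on random tables", {
  set.seed(14)
  for (i in 1:200) {
    tab <- contingency_table(sample(0:50, 1), sample(0:500, 1),
                             sample(1:50, 1), sample(0:500, 1))
    m <- compute_metrics(tab)
    if (!is.na(m$precision)) {
      expect_gte(m$f_measure + 1e-12, min(m$precision, m$recall))
      expect_lte(m$f_measure - 1e-12, max(m$precision, m$recall))
      if (m$precision > 0) expect_equal(m$nnr * m$precision / 100, 1)
    }
  }
})

test_that("weighted error rate matches its definition and scaling laws", {
  # perfect classifier
  expect_equal(weighted_error_rate(contingency_table(10, 0, 0, 90), 2, 3), 0)
  # retrieve-everything under balanced costs: mean of miss rate 0 and
  # fallout 1
  costs <- balanced_costs(0.1)
  expect_equal(
    weighted_error_rate(contingency_table(10, 90, 0, 0),
                        costs$cost_fn, costs$cost_fp), 0.5)
  # balanced costs reduce to the mean of miss rate and fallout
  tab <- contingency_table(30, 200, 10, 760)
  costs <- balanced_costs(40 / 1000)
  expect_equal(weighted_error_rate(tab, costs$cost_fn, costs$cost_fp),
               (10 / 40 + 200 / 960) / 2)
  set.seed(3)
  for (i in 1:50) {
    tab <- contingency_table(sample(0:30, 1), sample(0:300, 1),
                             sample(0:30, 1), sample(0:300, 1))
    cfn <- runif(1, 0.1, 50); cfp <- runif(1, 0.1, 50)
    # independent cost-sum oracle: per-document accumulation
    num <- sum(rep(cfn, tab$c)) + sum(rep(cfp, tab$b))
    den <- sum(rep(cfn, tab$a + tab$c)) + sum(rep(cfp, tab$b + tab$d))
    expected <- if (den == 0) 0 else num / den
    expect_equal(weighted_error_rate(tab, cfn, cfp), expected,
                 tolerance = 1e-12)
    # invariance under joint rescaling
    expect_equal(weighted_error_rate(tab, 7.3 * cfn, 7.3 * cfp),
                 weighted_error_rate(tab, cfn, cfp), tolerance = 1e-12)
  }
  expect_error(weighted_error_rate(tab, -1, 1), "positive")
})

test_that("split significance is the uncorrected chi-square association", {
  # no association: identical class proportions in both rows
  expect_equal(split_significance(contingency_table(10, 30, 20, 60)), 1,
               tolerance = 1e-9)
  # zero margin: nothing testable
  expect_equal(split_significance(contingency_table(0, 0, 20, 60)), 1)
  # extreme separation
  expect_lt(split_significance(contingency_table(100, 0, 0, 100)), 1e-10)
  # fixed table against the textbook statistic
  tab <- contingency_table(30, 70, 10, 90)
  n <- 200
  stat <- n * (30 * 90 - 70 * 10)^2 / (100 * 100 * 40 * 160)
  expect_equal(split_significance(tab),
               pchisq(stat, df = 1, lower.tail = FALSE), tolerance = 1e-12)
})
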