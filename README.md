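# hedgedev

Tools for developing and validating Boolean literature-search filters
("hedges") against labeled bibliographic corpora.

Search filters are pretested Boolean queries — e.g. PubMed Clinical
Queries — that retrieve a class of studies from MEDLINE. Developing one
requires a gold-standard corpus (every record hand-labeled relevant or
not), a way to score candidate query terms, and a strategy for combining
terms into a multi-term filter. The motivating use case is retrieving
*clinical examination* studies — studies quantifying the sensitivity and
specificity of symptoms and physical signs — a class with very low
prevalence (tens of relevant articles among tens of thousands), which is
what makes filter development statistically delicate.

`hedgedev` covers the whole cycle, for librarians, systematic reviewers
and informatics researchers:

* **Corpus handling** — MEDLINE flat-file and line-delimited JSON I/O,
  gold-standard label lists, and a seeded synthetic-corpus generator
  with class-conditional term occurrence or a planted Boolean rule.
* **Query engine** — a PubMed-style dialect: field tags `[tw]`, `[TIAB]`,
  `[ti]`, `[MeSH]` (with opt-in explosion and `:noexp`), `[sh]`, `[pt]`,
  explicit `*` truncation, quoted phrases, and `AND` / `OR` / binary
  `NOT` with precedence `NOT > AND > OR`.
* **Evaluation** — the standard retrieval 2×2 table

  |              | relevant | nonrelevant |
  |--------------|----------|-------------|
  | retrieved    | A        | B           |
  | missed       | C        | D           |

  with recall `A/(A+C)`, precision `A/(A+B)`, F-measure `2PR/(P+R)`,
  fallout `B/(B+D)` and number needed to read `1/P`.
* **Filter development** — recall/fallout threshold screening of
  candidate terms, exhaustive scoring of OR-combinations via cached
  retrieval-set unions, and **recursive partitioning**: greedy tree
  induction over Boolean term predicates, choosing at each node the term
  with the lowest cost-weighted error rate

  `(c_fn·C + c_fp·B) / (c_fn·(A+C) + c_fp·(B+D))`

  (default costs `c_fn = 1/prevalence`, `c_fp = 1/(1−prevalence)`),
  stopping a branch when the split's 2×2 association is no longer
  significant (chi-square, α = 0.05), enforcing a whole-tree recall
  floor (default 99%), and converting the tree to an AND/OR/NOT filter
  string.
* **Snowballing** — quantifying the recall gained by checking the
  reference lists of retrieved relevant articles.

## Worked example

Induce a multi-term filter from a synthetic training corpus in which
relevance is determined by the hidden rule `(t1 AND t2) OR t3` at ~2%
prevalence, with ten distractor terms:

```r
library(hedgedev)

vocab <- data.frame(
  term = c("t1", "t2", "t3", paste0("d", 1:10)), field = "abstract",
  p_relevant = 0,
  p_background = c(0.1, 0.1, 0.01, seq(0.05, 0.3, length.out = 10)))
cfg <- synthetic_config(5000, vocabulary = vocab,
                        planted_rule = "(t1[tw] AND t2[tw]) OR t3[tw]",
                        seed = 42)
lc <- generate_synthetic_corpus(cfg)
lc
#> <labeled_corpus> 5000 documents, 98 relevant (prevalence 0.0196)

cands <- candidate_terms(paste0(vocab$term, "[tw]"), lc)
slate <- screen_terms(cands, min_recall = 25, max_fallout = 75, mode = "or")
tree <- grow_rp_tree(lc, slate)
tree
#> <rp_tree> 5000 documents (98 relevant), costs fn=51.02 fp=1.02
#> split: t1[tw] (weighted error 0.2485, p = 1.85e-61)
#>   present:
#>     split: t2[tw] (weighted error 0.05997, p = 6.45e-101)
#>       present:
#>         <retrieve> 54 relevant / 0 nonrelevant
#>       absent:
#>         split: t3[tw] (weighted error 0, p = 6.55e-10)
#>           present:
#>             <retrieve> 4 relevant / 0 nonrelevant
#>           absent:
#>             <discard> 0 relevant / 435 nonrelevant
#>   absent:
#>     split: t3[tw] (weighted error 0, p = 6.78e-99)
#>       present:
#>         <retrieve> 40 relevant / 0 nonrelevant
#>       absent:
#>         <discard> 0 relevant / 4467 nonrelevant

filt <- tree_to_boolean(tree)
deparse_query(filt)
#> ((t1[tw] AND (t2[tw] OR t3[tw])) OR (t3[tw] NOT t1[tw]))

compute_metrics(build_contingency(lc, retrieve(lc, filt)))
#> recall 100%  precision 100%  F 100  fallout 0%  NNR 1
```

The tree splits first on `t1` (lowest cost-weighted error), reuses `t3`
in both sibling subtrees, and the extracted filter is extensionally
identical to the planted rule: recall 100%, precision 100%. The cost
weights (`fn=51.02`) show the false-negative cost inflated by
1/prevalence so the 98 relevant documents are not swamped by the 4,902
nonrelevant ones.

Evaluating shipped filter definitions against a labeled MEDLINE file:

```r
corp <- read_medline(system.file("extdata", "sample.medline",
                                 package = "hedgedev"))
lc <- load_labels(corpus = corp, text = c("10001", "10003"))
cmd_evaluate(lc, filters = builtin_filters()[c(1, 3, 7), ])
#>                   name recall precision f_measure nnr
#> 1 Diagnosis-subheading    100  66.66667  80.00000 1.5
#> 2       Dx-high-recall    100  66.66667  80.00000 1.5
#> 3            RP-filter     50 100.00000  66.66667 1.0
```

## Command line

```sh
Rscript inst/cli/hedgedev.R simulate --n-docs 10000 --prevalence 0.001 \
    --vocabulary vocab.csv --seed 7 --out runs/sim
Rscript inst/cli/hedgedev.R develop --corpus runs/sim/corpus.jsonl \
    --labels runs/sim/labels.txt --candidates terms.txt --out runs/dev
Rscript inst/cli/hedgedev.R evaluate --corpus runs/sim/corpus.jsonl \
    --labels runs/sim/labels.txt --filters filters.tsv --combinations
Rscript inst/cli/hedgedev.R augment --corpus runs/sim/corpus.jsonl \
    --labels runs/sim/labels.txt --filters filters.tsv --graph refs.tsv
```

See the methods vignette (`vignettes/filter-development.Rmd`) for the
model, its assumptions, parameter defaults, and known limitations.
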