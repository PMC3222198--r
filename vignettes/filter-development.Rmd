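---
title: "Developing Boolean search filters by screening, combination and recursive partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing Boolean search filters by screening, combination and recursive partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hedgedev)
```

## The problem

A search filter (hedge) is a Boolean query intended to retrieve one
class of studies from a bibliographic database. Development requires a
*labeled corpus*: every record judged relevant or nonrelevant against a
gold standard. Two features make the problem statistically awkward:

1. **Extreme class imbalance.** The target class is typically well
   under 0.5% of the corpus. Unweighted misclassification error would
   declare the empty filter near-optimal; every precision figure is
   pinned near zero by the base rate, so the number needed to read
   (NNR) rather than raw precision is the interpretable quantity.
2. **Boolean predictors.** Candidate predictors are themselves query
   terms — text words, MeSH headings, subheadings, publication types —
   so the fitted model must come back out as a query a bibliographic
   database can execute.

`hedgedev` implements the development cycle: score candidate
single-term filters, screen them by recall/fallout thresholds,
exhaustively score OR-combinations of a small screened slate, and — when
the slate is too large for exhaustive search — induce a multi-term
AND/OR filter by recursive partitioning with cost-weighted errors.

## Retrieval metrics

All measures derive from the 2×2 table crossing retrieval with
relevance (`build_contingency()`): recall $A/(A+C)$, precision
$A/(A+B)$, fallout $B/(B+D)$, $F = 2PR/(P+R)$ and $\mathrm{NNR} = 1/P$.
Recall, precision and fallout are reported in percent and the F-measure
is computed *on the percent scale*, following the convention of the
filter-development literature (an F of 0.26 next to a precision of
0.13%). Two deliberate edge-case choices:

* When nothing is retrieved ($A+B=0$), precision is **missing**, not
  zero, and NNR is infinite — an empty filter should never win a
  precision ranking by technicality.
* A corpus with no relevant documents is rejected outright
  (recall undefined), as is an all-relevant corpus (fallout undefined).

Report rounding mirrors the field's tables — whole-percent recall, two
decimals for precision/F, NNR to two significant figures up to 10 and
whole articles above — but full-precision values are always carried
alongside (`rounded_metrics()` never replaces the raw report).

## The query dialect

The engine implements the PubMed-style syntax that published filters
are written in, with documented approximations:

* Tokenization splits on any non-alphanumeric character and
  case-folds. There is **no stemming**: truncation is only ever the
  explicit trailing `*`, matching tokens by prefix.
* `[tw]` searches title ∪ abstract ∪ MeSH heading and subheading
  names. Real PubMed text-word scope also includes fields (e.g. author
  keywords) absent from this data model; this is a documented
  approximation, fixed so results are reproducible.
* `[MeSH]` is an exact heading-name match. Explosion (descendant
  headings) happens only when the caller supplies a hierarchy
  (`read_mesh_hierarchy()`); no hierarchy ships with the package, so
  the default is no explosion, and `:noexp` pins a leaf down even when
  a hierarchy is present.
* `NOT` is binary set-difference, as in database query languages; a
  query beginning with `NOT` is a parse error (no unrestricted
  complement exists in the dialect).
* `subheading` and `mesh` are accepted as aliases of `sh` and `MeSH`,
  since published filter strings use both spellings; untagged terms
  default to `[tw]`; automatic term mapping is deliberately not
  implemented — what you write is what is matched.

## Candidate screening and exhaustive combination

`screen_terms()` applies a recall floor and fallout cap in two modes:
the strict AND mode (default 25/50) producing the small slate whose
OR-combinations are enumerated exhaustively, and the loose OR mode
(default 25/75) producing the wider slate offered to the tree. The
strictness difference reflects the two consumers: exhaustive
enumeration is exponential in slate size (a hard budget cap, default
$10^6$ subsets, turns accidental blowups into an explicit error), while
the tree handles a wide slate gracefully because it is greedy.

Combination metrics are computed from unions of cached per-term
retrieval vectors, never by re-parsing and re-evaluating the OR query;
a property test asserts cell-identical agreement between the two
routes. `select_best()` ranks under three objectives (best recall with
a fallout cap, best precision with a recall floor, best F) with a
deterministic tie-break — higher recall, then lower fallout, then the
lexicographically smallest sorted label set — so results are invariant
to input order; published development tables never report ties, so the
tie-break is a package decision.

## Recursive partitioning

`grow_rp_tree()` induces a classification tree whose predictors are the
candidate term-filters:

1. **Split choice.** At each node, the candidate minimizing the
   cost-weighted error rate
   $(c_{fn} C + c_{fp} B)\,/\,(c_{fn}(A+C) + c_{fp}(B+D))$
   on the node's documents. Default costs are prevalence-balanced,
   $c_{fn} = 1/\pi$, $c_{fp} = 1/(1-\pi)$, under which the rate is the
   mean of the miss rate and the fallout — the weighting exists solely
   so the rare relevant class is not swamped. Both costs are
   configurable; the rate is invariant to their joint rescaling.
2. **Stopping.** A branch stops when the best split's 2×2 association
   is no longer significant at `alpha` (default 0.05). The test is
   Pearson's chi-square without continuity correction, falling back to
   the exact hypergeometric test when any expected cell is below 5; a
   zero margin returns $p = 1$ (nothing testable). Significance — not a
   cost-decrease criterion — is the stopping rule: with a recall-floor
   objective a split can be worth accepting even when both children
   would initially be classified "discard" (equal cost to the parent
   leaf), because descendants may later isolate a cheap pocket of
   relevant documents. A `max_depth` bound (default 10) guards against
   overfitting, which greedy induction on rare classes invites.
3. **Term reuse.** A term used on a path is removed from that path's
   slate but remains available in sibling subtrees — the same term can
   legitimately split both the present- and absent-side of an ancestor.
4. **Leaf classification and the recall floor.** Leaves are classified
   to minimize cost ($c_{fn} \cdot \text{rel} \ge c_{fp} \cdot
   \text{nonrel}$ retrieves; ties retrieve, favoring recall). If
   whole-tree recall then falls below `recall_floor` (default 99%),
   discard leaves containing relevant documents are flipped to
   retrieve, cheapest-cost-per-recall first, until the floor holds. The
   floor is a whole-tree constraint, not per-branch: per-branch
   enforcement would forbid any discard leaf that contains a single
   relevant document, i.e. forbid trees at all at 99%. Because flipping
   can always reach 100% recall, the floor is always attainable — the
   cost of an aggressive floor is precision, visible in the report, not
   a failure.
5. **Pruning.** Subtrees whose leaves all share one class are collapsed
   afterwards; every split in the returned tree genuinely separates
   retrieve- from discard-regions.

`tree_to_boolean()` converts the tree to a filter: the disjunction over
retrieve-leaves of each path's conditions, factored through the tree so
shared prefixes appear once, with the simplification
$T \cup (X \setminus T) = T \cup X$ applied where the present-child is a
pure retrieve-leaf. Extensional equivalence with the tree (on the
training corpus and on fresh corpora) is asserted by tests; syntactic
minimality is best-effort only. Two degenerate shapes are errors rather
than filters: a tree with no retrieve-leaf (empty filter) and a tree
whose absent-branch retrieves everything (would require unrestricted
negation, which the dialect cannot express).

## The synthetic-corpus generator

`generate_synthetic_corpus()` emulates the structure of a hand-labeled
bibliographic database: `n_docs` records, a gold-standard prevalence on
the order of 0.1%, and a vocabulary of single-token terms placed into
title, abstract, MeSH or publication-type fields with class-conditional
occurrence probabilities — or, for method validation, a planted Boolean
rule that *defines* the label (occurrences then drawn at each term's
background rate, labels optionally flipped with `label_noise`).
Everything is driven by one integer seed; identical configs produce
byte-identical corpora.

What it does **not** emulate: correlated term occurrences, realistic
title/abstract language (fields are token bags around a filler
stub), the MeSH hierarchy, temporal drift, or indexer inconsistency —
the known real-world failure mode where headings one would rely on are
applied to only a fraction of eligible articles. Passing tests on
synthetic corpora therefore demonstrate *algorithmic* correctness
(planted structure is recovered, metrics are exact, procedures are
deterministic), not expected field performance of any filter.

## Problem sizes and numerical choices

The validation suite runs at sizes chosen to exercise the estimators
without waste: oracle-equivalence and Boolean-law properties over 100
seeded corpora of 500 documents; planted-rule recovery over 20 seeded
corpora of 5,000 documents at ≈2% rule prevalence with 10 distractor
terms (success = recall 100% and precision ≥ 95%, required in ≥ 18 of
20); significance-test agreement with independently coded chi-square
and exact-tail oracles to $10^{-9}$ over 1,000 random tables spanning
both regimes. Cost arithmetic uses plain double precision; the only
tolerance anywhere is that oracle comparison bound.

Published worked-example cells are re-derived only where the printed
(recall, precision) pair is arithmetically consistent with the printed
F/NNR under the stated rounding; several printed cells were evidently
computed from unrounded values (e.g. an NNR of 778 printed beside a
precision of 0.13, where $1/0.0013 = 769$), and those are not asserted.

## Limitations

* The [tw] scope and tokenizer approximate, not replicate, PubMed; a
  filter validated here can behave differently against the live service
  (automatic term mapping, additional indexed fields, phrase handling).
* Greedy induction with significance stopping has no optimality
  guarantee; with many candidates and small gold standards, spurious
  splits at $\alpha = 0.05$ are expected a few percent of the time —
  the depth bound and pruning limit, but do not eliminate, overfitting.
  No cross-validation pruning is implemented.
* Reference-list augmentation treats the citation graph as given input;
  extracting references from full text is out of scope.
* Exact reproduction of corpus-level published results requires the
  original corpora, which are not redistributable; the package
  validates the machinery on synthetic data and on the published
  worked-example arithmetic instead.
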