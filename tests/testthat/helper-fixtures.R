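# Shared fixtures, built in code.

# A small handcrafted corpus exercising every searchable field.
tiny_corpus <- function() {
  bib_corpus(list(
    document("d1",
             title = "Accuracy of the clinical examination for heart failure",
             abstract = "Sensitivity and specificity of the third heart sound.",
             mesh = list(list(heading = "Heart Failure",
                              subheadings = "diagnosis", major = TRUE),
                         list(heading = "Physical Examination")),
             pub_types = "Journal Article"),
    document("d2",
             title = "MRI of the knee",
             abstract = "Imaging in meniscal tears.",
             mesh = list(list(heading = "Magnetic Resonance Imaging",
                              subheadings = "methods", major = FALSE)),
             pub_types = c("Journal Article", "Comparative Study")),
    document("d3",
             title = "Symptoms and signs in appendicitis",
             abstract = "",
             mesh = list(list(heading = "Appendicitis",
                              subheadings = c("diagnosis", "surgery"),
                              major = TRUE),
                         list(heading = "Medical History Taking")),
             pub_types = "Clinical Trial"),
    document("d4",
             title = "Specific criteria for diagnosing pneumonia clinically",
             abstract = "Clinical examination versus chest radiograph.",
             mesh = list(list(heading = "Pneumonia",
                              subheadings = "diagnosis")),
             pub_types = "Journal Article"),
    document("d5",
             title = "Treatment of hypertension",
             abstract = "Randomized trial of antihypertensive therapy.",
             mesh = list(list(heading = "Hypertension",
                              subheadings = "drug therapy")),
             pub_types = "Randomized Controlled Trial")
  ))
}

tiny_labeled <- function(relevant = c("d1", "d3", "d4")) {
  labeled_corpus(tiny_corpus(), relevant)
}

# Default vocabulary for randomized corpora: a few informative terms and
# label-independent distractors.
test_vocabulary <- function(n_distractors = 4) {
  rbind(
    data.frame(term = c("alpha", "beta", "gamma"),
               field = c("abstract", "title", "mesh"),
               p_relevant = c(0.85, 0.6, 0.3),
               p_background = c(0.05, 0.1, 0.15),
               stringsAsFactors = FALSE),
    if (n_distractors > 0)
      data.frame(term = paste0("noise", seq_len(n_distractors)),
                 field = "abstract",
                 p_relevant = 0.2, p_background = 0.2,
                 stringsAsFactors = FALSE))
}

random_corpus <- function(n = 500, prevalence = 0.1, seed = 1,
                          vocabulary = test_vocabulary()) {
  generate_synthetic_corpus(
    synthetic_config(n, prevalence, vocabulary, seed = seed))
}

medline_fixture_path <- function() {
  system.file("extdata", "sample.medline", package = "hedgedev")
}

# fixture mirroring a testing-database scenario: n_rel relevant articles,
# `missed` of them not retrieved, `recovered` of the missed ones cited by
# retrieved relevant articles
make_augment_fixture <- function(n_rel = 188, n_irrel = 300, missed = 4,
                                 recovered = 2) {
  rel_ids <- sprintf("R%03d", seq_len(n_rel))
  irrel_ids <- sprintf("N%03d", seq_len(n_irrel))
  docs <- lapply(c(rel_ids, irrel_ids), function(id)
    document(id, title = paste("article", id)))
  lc <- labeled_corpus(bib_corpus(docs), rel_ids)
  missed_ids <- utils::tail(rel_ids, missed)
  retrieved <- setdiff(c(rel_ids, utils::head(irrel_ids, 50)), missed_ids)
  graph <- citation_graph(stats::setNames(
    lapply(seq_len(recovered),
           function(i) c(missed_ids[i], "outside-corpus-id")),
    utils::head(rel_ids, recovered)))
  list(lc = lc, retrieved = retrieved, graph = graph,
       missed_ids = missed_ids)
}

# brute-force retrieval-set oracle: per-document evaluation
brute_retrieve <- function(corpus, query, hierarchy = NULL) {
  if (inherits(corpus, "labeled_corpus")) corpus <- corpus$corpus
  node <- if (is.character(query)) parse_query(query) else query
  keep <- vapply(corpus$docs, evaluate_query, logical(1),
                 node = node, hierarchy = hierarchy)
  corpus$ids[keep]
}
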