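test_that("tokenize splits sentences and normalizes tokens", {
  expect_identical(tokenize("Kinase binds substrate. It regulates transport."),
                   list(c("kinase", "binds", "substrate"),
                        c("it", "regulates", "transport")))
  expect_identical(tokenize(""), list())
  expect_identical(tokenize("   "), list())
  # edge punctuation is stripped, internal hyphens kept, numerals dropped
  expect_identical(tokenize("E3 ubiquitin-protein ligase (HECT-type)."),
                   list(c("e3", "ubiquitin-protein", "ligase", "hect-type")))
  expect_identical(tokenize("Binds 42 ions!"), list(c("binds", "ions")))
  expect_identical(tokenize("No terminal punctuation"),
                   list(c("no", "terminal", "punctuation")))
})

test_that("tokenizing a document's raw text reproduces its sentences", {
  co <- make_random_corpus(6, 12, seed = 3)
  for (doc in co$documents) {
    expect_identical(tokenize(doc$raw_text), doc$sentences)
  }
})

test_that("TF-IDF matches tf * ln(N/df) and its closed-form zeros", {
  # term in every document has weight 0; single-doc corpus is all zero
  co1 <- corpus(data.frame(entity_id = c("A", "B", "C"),
                           text = c("kinase binds.", "kinase acts.",
                                    "kinase kinase moves.")))
  td <- compute_tfidf(co1)
  expect_equal(unname(as.matrix(td)["kinase", ]), c(0, 0, 0))
  # 3-doc corpus, term in 1 doc with count 2 -> 2*ln(3)
  expect_equal(as.matrix(td)["moves", "C"], log(3))
  expect_equal(as.matrix(td)["kinase", "C"], 0)
  co_single <- corpus(data.frame(entity_id = "A", text = "kinase binds substrate."))
  expect_true(all(as.matrix(compute_tfidf(co_single)) == 0))
  # random corpus vs independent element-wise evaluation
  co <- make_random_corpus(8, 15, seed = 11)
  td2 <- compute_tfidf(co)
  oracle <- oracle_tfidf(co, rownames(as.matrix(td2)))
  expect_equal(unname(as.matrix(td2)), unname(oracle), tolerance = 1e-12)
})

test_that("TF-IDF weights are invariant under document reordering", {
  co <- make_random_corpus(7, 10, seed = 5)
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  df <- data.frame(entity_id = entity_ids(co)[perm],
                   text = vapply(co$documents[perm], `[[`, "", "raw_text"))
  td1 <- as.matrix(compute_tfidf(co))
  td2 <- as.matrix(compute_tfidf(corpus(df)))
  expect_equal(td1[rownames(td2), colnames(td2)], td2, tolerance = 1e-14)
})

test_that("vocabulary filters apply conjunctively and order terms by frequency", {
  co <- corpus(data.frame(
    entity_id = c("A", "B", "C"),
    text = c("protein kinase binds. It acts.",
             "protein transport moves.",
             "protein kinase regulates.")))
  # stopword removal
  v <- filter_vocabulary(co, filter_config(stopwords = "it"))
  expect_false("it" %in% v)
  # ubiquitous term removed at fraction boundary
  v <- filter_vocabulary(co, filter_config(max_doc_freq_fraction = 0.99))
  expect_false("protein" %in% v)
  expect_true("kinase" %in% v)
  # ordering: descending frequency, lexicographic ties
  v <- filter_vocabulary(co)
  expect_identical(v[1:2], c("protein", "kinase"))
  freq <- rowSums(as.matrix(build_tdm(co, v, "freq")))
  expect_true(all(diff(unname(freq)) <= 0))
  # whitelist restriction and empty-whitelist rejection
  v <- filter_vocabulary(co, filter_config(whitelist = c("kinase", "transport")))
  expect_setequal(v, c("kinase", "transport"))
  expect_error(filter_vocabulary(co, filter_config(whitelist = character())),
               "whitelist")
})

test_that("min_doc_freq matches a brute-force document-frequency count", {
  co <- make_random_corpus(20, 25, seed = 9)
  v <- filter_vocabulary(co, filter_config(min_doc_freq = 3))
  all_terms <- filter_vocabulary(co)
  df <- vapply(all_terms, function(t) {
    sum(vapply(seq_along(co$documents), function(d)
      oracle_term_count(co, t, d) > 0, TRUE))
  }, 0L)
  expect_setequal(v, all_terms[df >= 3])
})

test_that("filter composition is order-independent (conjunction)", {
  co <- make_random_corpus(12, 20, seed = 2)
  both <- filter_vocabulary(co, filter_config(min_doc_freq = 2,
                                              max_doc_freq_fraction = 0.8))
  one <- filter_vocabulary(co, filter_config(min_doc_freq = 2))
  two <- filter_vocabulary(co, filter_config(max_doc_freq_fraction = 0.8))
  expect_setequal(both, intersect(one, two))
})

test_that("term-document matrix counts equal a naive recount", {
  co <- corpus(data.frame(entity_id = c("A", "B"),
                          text = c("kinase binds kinase.", "transport moves.")))
  td <- build_tdm(co, "kinase", scheme = "freq")
  expect_equal(unname(as.matrix(td)["kinase", ]), c(2, 0))
  # tfidf scheme reproduces compute_tfidf restricted to the vocabulary
  co2 <- make_random_corpus(10, 14, seed = 4)
  vocab <- filter_vocabulary(co2)[1:8]
  td_f <- build_tdm(co2, vocab, scheme = "tfidf")
  full <- compute_tfidf(co2)
  expect_equal(as.matrix(td_f), as.matrix(full)[vocab, ], tolerance = 1e-14)
  # column sums equal per-document vocabulary token counts
  td_c <- build_tdm(co2, vocab, scheme = "freq")
  for (d in seq_along(co2$documents)) {
    expect_equal(sum(as.matrix(td_c)[, d]),
                 sum(vapply(vocab, oracle_term_count, 0L, corpus = co2,
                            doc_index = d)))
  }
  # absent vocabulary terms give an all-zero, flagged row
  td_a <- build_tdm(co, c("kinase", "zzz"), scheme = "freq")
  expect_equal(unname(as.matrix(td_a)["zzz", ]), c(0, 0))
  expect_identical(td_a$absent_terms, "zzz")
  expect_error(build_tdm(co, character()), "non-empty")
})

test_that("n-grams are counted within sentences only", {
  co <- corpus(data.frame(entity_id = "A",
                          text = "signal transduction pathway."))
  ng <- extract_ngrams(co, 2)
  expect_equal(ng[["signal transduction"]], 1L)
  expect_equal(ng[["transduction pathway"]], 1L)
  expect_equal(length(ng), 2L)
  # never across sentence boundaries; short sentences contribute nothing
  co2 <- corpus(data.frame(entity_id = "A", text = "alpha beta. gamma."))
  ng2 <- extract_ngrams(co2, 2)
  expect_identical(names(ng2), "alpha beta")
  expect_equal(length(extract_ngrams(co2, 3)), 0L)
  expect_error(extract_ngrams(co, 1), "n must be")
})

test_that("n-gram counts equal a sliding-window enumeration", {
  co <- make_random_corpus(5, 8, n_sentences = 3, sentence_len = 5, seed = 13)
  ng <- extract_ngrams(co, 2)
  expected <- new.env()
  for (doc in co$documents) for (sent in doc$sentences) {
    if (length(sent) < 2) next
    for (i in seq_len(length(sent) - 1)) {
      key <- paste(sent[i], sent[i + 1])
      expected[[key]] <- (if (is.null(expected[[key]])) 0L else expected[[key]]) + 1L
    }
  }
  expect_equal(length(ng), length(ls(expected)))
  for (key in ls(expected)) expect_equal(ng[[key]], expected[[key]])
})
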