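# Independent brute-force oracles, deliberately implemented differently
# from the package internals they check.

# random corpus of nonsense words for oracle-equivalence tests
make_random_corpus <- function(n_docs, vocab_size, n_sentences = 4,
                               sentence_len = 6, seed = 1) {
  words <- sprintf("w%02d", seq_len(vocab_size))
  withr::with_seed(seed, {
    texts <- vapply(seq_len(n_docs), function(i) {
      sents <- vapply(seq_len(n_sentences), function(s) {
        paste0(paste(sample(words, sentence_len, replace = TRUE),
                     collapse = " "), ".")
      }, "")
      paste(sents, collapse = " ")
    }, "")
  })
  corpus(data.frame(entity_id = sprintf("E%02d", seq_len(n_docs)),
                    text = texts, stringsAsFactors = FALSE))
}

# wrap a bare matrix as a term-document matrix object
make_tdm <- function(mat, scheme = "freq") {
  structure(list(weights = mat, scheme = scheme,
                 term_frequency = stats::setNames(as.integer(round(rowSums(mat))),
                                                  rownames(mat)),
                 absent_terms = character()),
            class = "term_document_matrix")
}

# exhaustive sentence-scan co-occurrence counts: loop over every pair of
# vocabulary terms and every sentence of every document
oracle_cooccurrence <- function(corpus, vocabulary) {
  sentences <- unlist(lapply(corpus$documents, `[[`, "sentences"),
                      recursive = FALSE)
  out <- list()
  nv <- length(vocabulary)
  for (i in seq_len(nv - 1L)) {
    for (j in (i + 1L):nv) {
      count <- 0L
      for (sent in sentences) {
        if (vocabulary[i] %in% sent && vocabulary[j] %in% sent)
          count <- count + 1L
      }
      if (count > 0L) {
        key <- paste(sort(c(vocabulary[i], vocabulary[j])), collapse = "|")
        out[[key]] <- count
      }
    }
  }
  out
}

# naive Pearson correlation from the definition (no stats::cor)
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sx <- sqrt(sum((x - mx)^2)); sy <- sqrt(sum((y - my)^2))
  if (sx == 0 || sy == 0) return(NA_real_)
  sxy / (sx * sy)
}

# per-document token recount straight from the raw text
oracle_term_count <- function(corpus, term, doc_index) {
  toks <- unlist(corpus$documents[[doc_index]]$sentences)
  sum(toks == term)
}

# tf * ln(N/df) evaluated independently, element by element
oracle_tfidf <- function(corpus, terms) {
  n <- length(corpus$documents)
  sapply(seq_len(n), function(d) {
    sapply(terms, function(t) {
      df <- sum(vapply(seq_len(n), function(dd)
        oracle_term_count(corpus, t, dd) > 0, TRUE))
      tf <- oracle_term_count(corpus, t, d)
      if (df == 0) 0 else tf * log(n / df)
    })
  })
}

# adjusted Rand index from the contingency-table formula
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# independent re-implementation of the bootstrap resample-and-count loop:
# same seed and resampling order, but own distance, own subtree
# enumeration via recursive descent
oracle_bootstrap_bp <- function(mat, n_boot, seed, target_sets) {
  dist_of <- function(m) {
    n <- nrow(m)
    D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      r <- oracle_pearson(m[i, ], m[j, ])
      D[i, j] <- if (is.na(r)) 2 else 1 - r
    }
    stats::as.dist(D)
  }
  leafsets <- function(hc) {
    labels <- hc$labels
    collect <- function(node) {
      if (node < 0) return(labels[-node])
      c(collect(hc$merge[node, 1]), collect(hc$merge[node, 2]))
    }
    vapply(seq_len(nrow(hc$merge)), function(i)
      paste(sort(collect(i)), collapse = "|"), "")
  }
  keys <- vapply(target_sets, function(s) paste(sort(s), collapse = "|"), "")
  hits <- integer(length(keys))
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
      hc <- stats::hclust(dist_of(mat[, idx, drop = FALSE]), method = "average")
      present <- leafsets(hc)
      hits <- hits + (keys %in% present)
    }
  })
  hits / n_boot
}

# planted-theme fixture at the standard study conditions; vocabulary is
# taken through the ubiquity filter that removes the generic background
# words, as in the standard analysis pipeline
planted_fixture <- function(seed = 7) {
  sim <- generate_corpus(theme_spec(seed = seed))
  vocab <- filter_vocabulary(sim$corpus,
                             filter_config(max_doc_freq_fraction = 0.5))
  truth <- rep(names(sim$theme_words), lengths(sim$theme_words))
  names(truth) <- unlist(sim$theme_words)
  list(sim = sim, corpus = sim$corpus, vocab = vocab, truth = truth)
}

# leaf sets of the base dendrogram's internal nodes, in merge order,
# derived from the hclust merge matrix by recursive descent
.subtree_sets_for_test <- function(tg) {
  hc <- tg$hclust
  labels <- hc$labels
  collect <- function(node) {
    if (node < 0) return(labels[-node])
    c(collect(hc$merge[node, 1]), collect(hc$merge[node, 2]))
  }
  lapply(seq_len(nrow(hc$merge)), collect)
}

# compare two run manifests ignoring the timestamp and path-valued fields
# (the runs live in different directories by construction)
expect_equivalent_manifests <- function(p1, p2) {
  strip <- function(p) {
    m <- jsonlite::read_json(p)
    m$timestamp <- NULL
    m$inputs <- NULL
    for (f in c("out_dir", "corpus", "network", "config", "graph", "corpora"))
      m$parameters[[f]] <- NULL
    m
  }
  testthat::expect_identical(strip(p1), strip(p2))
}
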