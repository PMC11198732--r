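#' Segment free text into sentences of normalized word tokens
#'
#' Sentences are split on runs of terminal punctuation (`.`, `!`, `?`)
#' followed by whitespace or end of string. Tokens are produced by splitting
#' each sentence on whitespace, lowercasing, and stripping punctuation from
#' the token edges; internal punctuation is preserved so hyphenated
#' biomedical compounds ("ubiquitin-protein") stay whole. Empty tokens and
#' tokens consisting only of digits are dropped.
#'
#' @param raw_text A character scalar (may be empty).
#' @return A list of character vectors, one per sentence, in text order.
#'   An empty or whitespace-only input yields an empty list.
#' @examples
#' tokenize("Kinase binds substrate. It regulates transport.")
#' @export
tokenize <- function(raw_text) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L)
  if (is.na(raw_text) || !nzchar(trimws(raw_text))) return(list())
  if (!validUTF8(raw_text)) stop("raw_text is not valid UTF-8")
  sents <- strsplit(raw_text, "[.!?]+([[:space:]]+|$)")[[1L]]
  out <- lapply(sents, function(s) {
    toks <- strsplit(trimws(s), "[[:space:]]+")[[1L]]
    toks <- tolower(toks)
    toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
    toks <- toks[nzchar(toks)]
    toks[!grepl("^[0-9]+$", toks)]
  })
  out[vapply(out, length, 1L) > 0L]
}

#' Vocabulary filter configuration
#'
#' Bundles the combinable filters applied before network construction. All
#' enabled filters compose conjunctively: a term survives only if it passes
#' every one of them.
#'
#' @param stopwords Character vector of terms to exclude (lowercased).
#' @param min_doc_freq Minimum document frequency (integer >= 0). Uses the
#'   background table's document frequencies when `background` is supplied,
#'   otherwise the corpus's own.
#' @param max_doc_freq_fraction Maximum allowed document frequency as a
#'   fraction of the number of documents, in (0, 1]. Removes ubiquitous
#'   terms ("protein", "gene") that carry little signal.
#' @param min_tfidf Minimum term-level TF-IDF score, or `NULL` to disable.
#'   The term-level score is the sum over documents of tf * ln(N/df); when a
#'   background table with TF-IDF scores is supplied those are used instead.
#' @param whitelist Character vector restricting the vocabulary (e.g. a
#'   curated Gene-Ontology-derived word list), or `NULL` for no restriction.
#'   An empty whitelist is rejected: it would always yield an empty
#'   vocabulary.
#' @param min_token_length Minimum number of characters per term.
#' @param background A `background_stats` object (see [read_background()]),
#'   or `NULL` to use corpus-internal statistics.
#' @param top_k_terms Keep only the `k` most frequent surviving terms, or
#'   `NULL` to keep all.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(stopwords = character(),
                          min_doc_freq = 0L,
                          max_doc_freq_fraction = 1,
                          min_tfidf = NULL,
                          whitelist = NULL,
                          min_token_length = 1L,
                          background = NULL,
                          top_k_terms = NULL) {
  stopifnot(is.character(stopwords),
            length(min_doc_freq) == 1L, min_doc_freq >= 0,
            length(max_doc_freq_fraction) == 1L,
            max_doc_freq_fraction > 0, max_doc_freq_fraction <= 1,
            is.null(min_tfidf) || (length(min_tfidf) == 1L && min_tfidf >= 0),
            length(min_token_length) == 1L, min_token_length >= 1,
            is.null(top_k_terms) || (length(top_k_terms) == 1L && top_k_terms >= 1))
  if (!is.null(whitelist) && length(whitelist) == 0L)
    stop("whitelist is set but empty: it would always yield an empty vocabulary")
  if (!is.null(background) && !inherits(background, "background_stats"))
    stop("background must be a background_stats object")
  structure(list(stopwords = tolower(stopwords),
                 min_doc_freq = as.integer(min_doc_freq),
                 max_doc_freq_fraction = max_doc_freq_fraction,
                 min_tfidf = min_tfidf,
                 whitelist = if (is.null(whitelist)) NULL else tolower(whitelist),
                 min_token_length = as.integer(min_token_length),
                 background = background,
                 top_k_terms = if (is.null(top_k_terms)) NULL else as.integer(top_k_terms)),
            class = "filter_config")
}

# per-document token vectors (flattened over sentences)
.doc_tokens <- function(doc) unlist(doc$sentences, use.names = FALSE)

# terms x documents raw count matrix over the full corpus vocabulary
.count_matrix <- function(corpus, vocabulary = NULL) {
  docs <- corpus$documents
  tok <- lapply(docs, .doc_tokens)
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(unlist(tok, use.names = FALSE)))
  }
  m <- matrix(0, nrow = length(vocabulary), ncol = length(docs),
              dimnames = list(vocabulary,
                              vapply(docs, function(d) d$entity_id, "")))
  for (j in seq_along(tok)) {
    tb <- table(tok[[j]])
    hit <- intersect(names(tb), vocabulary)
    if (length(hit)) m[hit, j] <- as.numeric(tb[hit])
  }
  m
}

# order terms by descending corpus frequency, ties lexicographic
.order_terms <- function(terms, freq) {
  terms[order(-freq, terms, method = "radix")]
}

#' Filter and order the corpus vocabulary
#'
#' Applies every enabled filter in `config` (conjunctively) and returns the
#' surviving terms ordered by descending total corpus frequency, ties broken
#' lexicographically. If `top_k_terms` is set the ordered list is truncated
#' to `k` terms.
#'
#' Document-frequency and TF-IDF thresholds are evaluated against the
#' background table when `config$background` is supplied, otherwise against
#' the corpus itself.
#'
#' @param corpus A `corpus` object.
#' @param config A [filter_config()] object.
#' @return Character vector: the ordered vocabulary.
#' @export
filter_vocabulary <- function(corpus, config = filter_config()) {
  stopifnot(inherits(corpus, "corpus"), inherits(config, "filter_config"))
  if (!is.null(config$whitelist) && length(config$whitelist) == 0L)
    stop("whitelist is set but empty: it would always yield an empty vocabulary")
  cm <- .count_matrix(corpus)
  if (nrow(cm) == 0L) return(character())
  terms <- rownames(cm)
  tf <- rowSums(cm)
  df_corpus <- rowSums(cm > 0)
  n_corpus <- ncol(cm)

  keep <- nchar(terms) >= config$min_token_length
  keep <- keep & !(terms %in% config$stopwords)
  if (!is.null(config$whitelist)) keep <- keep & (terms %in% config$whitelist)

  bg <- config$background
  if (!is.null(bg) && length(bg$doc_freq) > 0L) {
    df <- ifelse(terms %in% names(bg$doc_freq), bg$doc_freq[terms], 0)
    n_docs <- bg$n_documents
  } else {
    df <- df_corpus
    n_docs <- n_corpus
  }
  keep <- keep & df >= config$min_doc_freq
  keep <- keep & (df / max(n_docs, 1L)) <= config$max_doc_freq_fraction

  if (!is.null(config$min_tfidf)) {
    if (!is.null(bg) && length(bg$tfidf) > 0L) {
      score <- ifelse(terms %in% names(bg$tfidf), bg$tfidf[terms], 0)
    } else {
      score <- ifelse(df_corpus > 0, tf * log(n_corpus / df_corpus), 0)
    }
    keep <- keep & score >= config$min_tfidf
  }

  vocab <- .order_terms(terms[keep], tf[keep])
  if (!is.null(config$top_k_terms)) vocab <- utils::head(vocab, config$top_k_terms)
  vocab
}

#' Build a term-document matrix
#'
#' Rows are `vocabulary` terms (in the given order), columns are documents
#' in corpus order. Under `scheme = "freq"` entries are raw within-document
#' token counts; under `scheme = "tfidf"` each count is weighted by
#' ln(N/df) where N is the number of documents and df the number of
#' documents containing the term. Vocabulary terms absent from the corpus
#' yield all-zero rows (kept, and flagged in the `absent_terms` attribute).
#'
#' @param corpus A `corpus` object.
#' @param vocabulary Non-empty character vector of terms.
#' @param scheme `"freq"` or `"tfidf"`.
#' @return An object of class `term_document_matrix`: a list with the
#'   numeric `weights` matrix, the `scheme`, and integer `term_frequency`
#'   (total corpus counts, used downstream as node frequencies).
#' @export
build_tdm <- function(corpus, vocabulary, scheme = c("freq", "tfidf")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(corpus, "corpus"))
  if (length(vocabulary) == 0L) stop("vocabulary must be non-empty")
  if (anyDuplicated(vocabulary)) stop("vocabulary contains duplicated terms")
  counts <- .count_matrix(corpus, vocabulary = vocabulary)
  term_freq <- as.integer(round(rowSums(counts)))
  names(term_freq) <- rownames(counts)
  absent <- rownames(counts)[rowSums(counts) == 0]
  weights <- counts
  if (scheme == "tfidf") {
    n <- ncol(counts)
    df <- rowSums(counts > 0)
    idf <- ifelse(df > 0, log(n / df), 0)
    weights <- counts * idf
  }
  structure(list(weights = weights, scheme = scheme,
                 term_frequency = term_freq, absent_terms = absent),
            class = "term_document_matrix")
}

#' @export
as.matrix.term_document_matrix <- function(x, ...) x$weights

#' @export
dim.term_document_matrix <- function(x) dim(x$weights)

#' @export
print.term_document_matrix <- function(x, ...) {
  cat(sprintf("term_document_matrix: %d terms x %d documents (scheme=%s)\n",
              nrow(x$weights), ncol(x$weights), x$scheme))
  invisible(x)
}

#' TF-IDF term-document matrix over the full corpus vocabulary
#'
#' Weight(t, d) = tf(t, d) * ln(N / df(t)), with tf the raw count of term t
#' in document d, N the number of documents and df(t) the number of
#' documents containing t. Natural logarithm, no length normalization. A
#' term present in every document has weight 0 everywhere; in a
#' single-document corpus all weights are 0.
#'
#' @param corpus A `corpus` object with at least one document.
#' @return A `term_document_matrix` with `scheme = "tfidf"`; terms ordered
#'   by descending corpus frequency (ties lexicographic).
#' @export
compute_tfidf <- function(corpus) {
  stopifnot(inherits(corpus, "corpus"))
  if (length(corpus$documents) < 1L) stop("corpus must contain at least one document")
  cm <- .count_matrix(corpus)
  if (nrow(cm) == 0L) stop("corpus contains no tokens")
  vocab <- .order_terms(rownames(cm), rowSums(cm))
  build_tdm(corpus, vocab, scheme = "tfidf")
}

#' Count n-grams within sentences
#'
#' n-grams are counted inside sentences only and never span a sentence
#' boundary; sentences shorter than `n` contribute nothing. The key of each
#' n-gram is its tokens joined by a single space.
#'
#' @param corpus A `corpus` object.
#' @param n Integer order of the n-grams, at least 2.
#' @return Named integer vector of corpus-wide n-gram counts, ordered by
#'   descending count (ties lexicographic).
#' @export
extract_ngrams <- function(corpus, n) {
  stopifnot(inherits(corpus, "corpus"))
  if (length(n) != 1L || is.na(n) || n < 2) stop("n must be an integer >= 2")
  n <- as.integer(n)
  grams <- character()
  for (doc in corpus$documents) {
    for (sent in doc$sentences) {
      L <- length(sent)
      if (L < n) next
      for (i in seq_len(L - n + 1L)) {
        grams <- c(grams, paste(sent[i:(i + n - 1L)], collapse = " "))
      }
    }
  }
  if (length(grams) == 0L) return(stats::setNames(integer(), character()))
  tb <- table(grams)
  counts <- as.integer(tb)
  names(counts) <- names(tb)
  counts[order(-counts, names(counts), method = "radix")]
}
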