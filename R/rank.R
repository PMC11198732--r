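#' Important words of a network
#'
#' Ranks the nodes of a word network by corpus frequency or by weighted
#' degree and returns the top `k` with their criterion value as importance
#' weight. Ties are broken lexicographically; if `k` exceeds the node count
#' all nodes are returned.
#'
#' @param network A non-empty `word_network`.
#' @param k Number of words to return, at least 1.
#' @param criterion `"frequency"` (corpus counts, the default) or
#'   `"degree"` (sum of incident edge weights).
#' @return data.frame with columns `term` and `weight`, descending.
#' @export
important_words <- function(network, k = 10L,
                            criterion = c("frequency", "degree")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(network, "word_network"))
  if (length(k) != 1L || is.na(k) || k < 1) stop("k must be an integer >= 1")
  g <- network$graph
  if (igraph::vcount(g) == 0L) stop("network has no nodes")
  terms <- igraph::V(g)$name
  w <- if (criterion == "frequency") {
    as.numeric(igraph::V(g)$frequency)
  } else {
    as.numeric(igraph::strength(g, weights = igraph::E(g)$weight))
  }
  ord <- order(-w, terms, method = "radix")
  utils::head(data.frame(term = terms[ord], weight = w[ord],
                         stringsAsFactors = FALSE), as.integer(k))
}

# accept a data.frame(term, weight) or a named numeric vector
.importance_vector <- function(important) {
  if (is.data.frame(important)) {
    stopifnot(all(c("term", "weight") %in% names(important)))
    stats::setNames(as.numeric(important$weight), important$term)
  } else if (is.numeric(important) && !is.null(names(important))) {
    important
  } else {
    stop("important must be a data.frame(term, weight) or a named numeric vector")
  }
}

#' Score and prioritize entities by important-word content
#'
#' The score of an entity is the weighted count of important words in its
#' description: sum over important words w of count(w in the entity's
#' tokens) * weight(w). With `normalization = "by_length"` the score is
#' divided by the entity's total token count (an entity with no tokens
#' scores 0 either way). Every queried entity appears in the result, and
#' scores do not depend on document order.
#'
#' @param corpus A `corpus` object.
#' @param important Non-empty important-word list: a data.frame with
#'   columns `term` and `weight` (as returned by [important_words()]) or a
#'   named numeric vector of weights.
#' @param normalization `"none"` (default) or `"by_length"`.
#' @return An object of class `entity_ranking`: list with `scores` (a
#'   data.frame of `entity_id`, `score`, `top_terms`, ordered by descending
#'   score, ties by id), `important_words`, and `normalization`. The
#'   `top_terms` column lists the important words found in each entity's
#'   text, largest contribution first, joined by `";"`.
#' @export
score_entities <- function(corpus, important,
                           normalization = c("none", "by_length")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(corpus, "corpus"))
  iw <- .importance_vector(important)
  if (length(iw) == 0L) stop("important word list must be non-empty")
  ids <- entity_ids(corpus)
  scores <- numeric(length(ids))
  top_terms <- character(length(ids))
  for (i in seq_along(corpus$documents)) {
    toks <- .doc_tokens(corpus$documents[[i]])
    if (length(toks) == 0L) next
    counts <- vapply(names(iw), function(w) sum(toks == w), 0)
    contrib <- counts * iw
    s <- sum(contrib)
    if (normalization == "by_length") s <- s / length(toks)
    scores[i] <- s
    present <- names(iw)[counts > 0]
    if (length(present)) {
      ord <- order(-contrib[counts > 0], present, method = "radix")
      top_terms[i] <- paste(present[ord], collapse = ";")
    }
  }
  df <- data.frame(entity_id = ids, score = scores, top_terms = top_terms,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$entity_id, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(scores = df,
                 important_words = data.frame(term = names(iw),
                                              weight = as.numeric(iw),
                                              stringsAsFactors = FALSE),
                 normalization = normalization),
            class = "entity_ranking")
}

#' @export
print.entity_ranking <- function(x, ...) {
  cat(sprintf("entity_ranking: %d entities (normalization=%s)\n",
              nrow(x$scores), x$normalization))
  print(utils::head(x$scores))
  invisible(x)
}

#' Write an entity ranking as TSV
#' @param ranking An `entity_ranking` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "entity_ranking"))
  df <- ranking$scores
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("entity_id\tscore\ttop_terms",
               sprintf("%s\t%.10g\t%s", df$entity_id, df$score, df$top_terms)),
             con, useBytes = TRUE)
  invisible(path)
}
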