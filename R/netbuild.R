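## Word networks: weighted undirected graphs over terms, built either from
## the correlation of term profiles across documents or from sentence-level
## co-occurrence counts. Values below the user threshold are dropped, which
## realizes the "set to zero" rule as edge absence in a sparse graph.

.new_word_network <- function(graph, metric, threshold, sources,
                              cluster_method = NULL, cluster_seed = NULL) {
  structure(list(graph = graph, metric = metric, threshold = threshold,
                 sources = sources, cluster_method = cluster_method,
                 cluster_seed = cluster_seed),
            class = "word_network")
}

#' @export
print.word_network <- function(x, ...) {
  cat(sprintf("word_network: %d nodes, %d edges (metric=%s, threshold=%s, sources=%s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$metric, format(x$threshold), paste(x$sources, collapse = ",")))
  invisible(x)
}

#' Node table of a word network
#' @param network A `word_network`.
#' @return data.frame with columns `term`, `frequency`, `cluster` (NA until
#'   [community_detect()] has been run).
#' @export
network_nodes <- function(network) {
  stopifnot(inherits(network, "word_network"))
  g <- network$graph
  cl <- if ("cluster" %in% igraph::vertex_attr_names(g))
    igraph::V(g)$cluster else rep(NA_integer_, igraph::vcount(g))
  out <- data.frame(term = igraph::V(g)$name,
                    frequency = igraph::V(g)$frequency,
                    cluster = cl,
                    stringsAsFactors = FALSE)
  out <- out[order(out$term, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Edge table of a word network
#' @param network A `word_network`.
#' @return data.frame with columns `from`, `to`, `weight`; `from < to`
#'   lexicographically, rows ordered by (`from`, `to`).
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "word_network"))
  g <- network$graph
  if (igraph::ecount(g) == 0L)
    return(data.frame(from = character(), to = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  el <- igraph::as_edgelist(g)
  a <- pmin(el[, 1L], el[, 2L]); b <- pmax(el[, 1L], el[, 2L])
  out <- data.frame(from = a, to = b, weight = igraph::E(g)$weight,
                    stringsAsFactors = FALSE)
  out <- out[order(out$from, out$to, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# assemble an undirected weighted graph from a symmetric weight matrix,
# keeping entries >= threshold and excluding NA (zero-variance) pairs
.graph_from_weights <- function(W, freq, threshold) {
  terms <- rownames(W)
  keep <- !is.na(W) & W >= threshold
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(terms), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = terms)
  g <- igraph::set_vertex_attr(g, "frequency", value = as.numeric(freq[terms]))
  if (nrow(idx) > 0L) {
    ord <- order(terms[idx[, 1L]], terms[idx[, 2L]], method = "radix")
    idx <- idx[ord, , drop = FALSE]
    g <- igraph::add_edges(g, rbind(terms[idx[, 1L]], terms[idx[, 2L]]),
                           weight = W[idx])
  }
  g
}

#' Correlation network of terms
#'
#' Edge weight between two terms is the correlation of their weight rows
#' across documents of the term-document matrix. Pairs whose correlation
#' falls below `threshold` are omitted. Terms with zero variance across
#' documents have undefined correlation and are kept as isolated nodes.
#'
#' @param tdm A `term_document_matrix` with at least 2 terms and 2
#'   documents.
#' @param threshold Correlation cutoff in \[-1, 1\]; edges with weight below
#'   it are dropped.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A `word_network` with `metric = "correlation"`; node attribute
#'   `frequency` carries the total corpus counts from the matrix.
#' @export
correlation_network <- function(tdm, threshold = 0.3,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(tdm, "term_document_matrix"))
  W <- tdm$weights
  if (ncol(W) < 2L) stop("correlation is undefined for fewer than 2 documents")
  if (nrow(W) < 2L) stop("need at least 2 terms to build a network")
  if (threshold < -1 || threshold > 1) stop("threshold must be in [-1, 1]")
  C <- suppressWarnings(stats::cor(t(W), method = method))
  C <- pmin(pmax(C, -1), 1)  # guard against rounding just outside [-1, 1]
  g <- .graph_from_weights(C, tdm$term_frequency, threshold)
  .new_word_network(g, metric = "correlation", threshold = threshold,
                    sources = "tdm")
}

#' Sentence co-occurrence network of terms
#'
#' Edge weight between two terms is the number of sentences, pooled over
#' every document of the corpus, that contain both terms at least once;
#' multiplicity within a sentence counts once. With `unit = "document"` the
#' count is instead the number of documents in which both terms appear
#' anywhere. Pairs with weight below `threshold` are omitted.
#'
#' @param corpus A `corpus` object.
#' @param vocabulary Non-empty character vector of terms to include as
#'   nodes.
#' @param threshold Integer count cutoff, at least 1.
#' @param unit Co-occurrence unit: `"sentence"` (default) or `"document"`.
#' @param source Source tag recorded on the network; defaults to the
#'   corpus's tag.
#' @return A `word_network` with `metric = "cooccurrence"`; weights are
#'   non-negative integers.
#' @export
cooccurrence_network <- function(corpus, vocabulary, threshold = 1L,
                                 unit = c("sentence", "document"),
                                 source = corpus$source) {
  unit <- match.arg(unit)
  stopifnot(inherits(corpus, "corpus"))
  if (length(vocabulary) == 0L) stop("vocabulary must be non-empty")
  if (length(threshold) != 1L || is.na(threshold) || threshold < 1)
    stop("threshold must be an integer >= 1")
  threshold <- as.integer(threshold)
  vocabulary <- unique(vocabulary)

  units <- if (unit == "sentence") {
    unlist(lapply(corpus$documents, `[[`, "sentences"), recursive = FALSE)
  } else {
    lapply(corpus$documents, .doc_tokens)
  }
  inc <- matrix(0L, nrow = length(units), ncol = length(vocabulary),
                dimnames = list(NULL, vocabulary))
  for (i in seq_along(units)) {
    hit <- intersect(unique(units[[i]]), vocabulary)
    if (length(hit)) inc[i, hit] <- 1L
  }
  counts <- if (length(units)) crossprod(inc) else
    matrix(0, length(vocabulary), length(vocabulary),
           dimnames = list(vocabulary, vocabulary))
  storage.mode(counts) <- "double"
  freq <- build_tdm(corpus, vocabulary, scheme = "freq")$term_frequency
  g <- .graph_from_weights(counts, freq, threshold)
  .new_word_network(g, metric = "cooccurrence", threshold = threshold,
                    sources = source)
}

# run fn with a locally seeded RNG, restoring the caller's stream
.with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  fn()
}

#' Detect word communities in a network
#'
#' Assigns every node exactly one cluster label. `"greedy_modularity"` uses
#' greedy modularity optimization; `"label_propagation"` uses label
#' propagation (seeded for reproducibility). Isolated nodes each form their
#' own singleton cluster. Negative-weight edges (possible in correlation
#' networks with a negative threshold) are excluded from the modularity
#' computation, since modularity is undefined for negative weights.
#'
#' @param network A non-empty `word_network`.
#' @param method `"greedy_modularity"` or `"label_propagation"`.
#' @param seed Integer RNG seed recorded in the network metadata.
#' @return The network with the node attribute `cluster` filled with
#'   integer labels.
#' @export
community_detect <- function(network,
                             method = c("greedy_modularity", "label_propagation"),
                             seed = 42L) {
  stopifnot(inherits(network, "word_network"))
  if (identical(method, c("greedy_modularity", "label_propagation")))
    method <- "greedy_modularity"
  if (length(method) != 1L || !method %in% c("greedy_modularity", "label_propagation"))
    stop("unknown community detection method: ",
         paste(as.character(method), collapse = ","))
  g <- network$graph
  if (igraph::vcount(g) == 0L) stop("network has no nodes")
  gpos <- igraph::delete_edges(g, igraph::E(g)[igraph::E(g)$weight < 0])
  membership <- .with_seed(seed, function() {
    if (method == "greedy_modularity") {
      comm <- igraph::cluster_fast_greedy(gpos, weights = igraph::E(gpos)$weight)
      # among merge steps tied for maximal modularity, cut at the coarsest
      # partition so structureless graphs collapse to a single community
      mods <- comm$modularity
      k <- igraph::vcount(gpos) - max(which(mods >= max(mods) - 1e-12)) + 1L
      as.integer(igraph::cut_at(comm, no = k))
    } else {
      as.integer(igraph::membership(
        igraph::cluster_label_prop(gpos, weights = igraph::E(gpos)$weight)))
    }
  })
  network$graph <- igraph::set_vertex_attr(g, "cluster", value = membership)
  network$cluster_method <- method
  network$cluster_seed <- as.integer(seed)
  network
}
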