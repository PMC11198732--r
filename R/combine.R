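## Combining word networks inferred from different text sources (RefSeq vs
## enrichment-result descriptions, two experimental conditions, ...) by set
## union or intersection of their node and edge sets.

# edge table with canonical (from < to) keys and the network's source tag
.edge_table <- function(network) {
  e <- network_edges(network)
  e$key <- paste(e$from, e$to, sep = "\r")
  e
}

.source_tag <- function(network) paste(network$sources, collapse = "+")

#' Merge word networks by union or intersection
#'
#' Union keeps every node and edge present in any input; intersection keeps
#' only those present in all inputs. Where an edge occurs in several inputs
#' its merged weight is combined by `weight_rule` (default: `max` for
#' union, so a strong edge is never lost; `min` for intersection, the
#' conservative choice). Each merged edge records the contributing source
#' tags in its `sources` attribute; node frequencies are summed across the
#' inputs containing the node (the inputs are counts over distinct
#' corpora). All inputs must share the same metric kind.
#'
#' @param networks List of at least 2 `word_network` objects.
#' @param mode `"union"` or `"intersection"`.
#' @param weight_rule `"max"`, `"mean"`, or `"min"`; `NULL` picks the
#'   mode-specific default.
#' @return A merged `word_network`; its `threshold` is the minimum of the
#'   input thresholds and its `sources` the concatenation of the input
#'   tags.
#' @export
merge_networks <- function(networks, mode = c("union", "intersection"),
                           weight_rule = NULL) {
  mode <- match.arg(mode)
  if (!is.list(networks) || length(networks) < 2L)
    stop("need at least 2 networks to merge")
  for (n in networks) stopifnot(inherits(n, "word_network"))
  metrics <- unique(vapply(networks, function(n) n$metric, ""))
  if (length(metrics) > 1L)
    stop("cannot merge networks of different metric kinds: ",
         paste(metrics, collapse = " vs "))
  if (is.null(weight_rule))
    weight_rule <- if (mode == "union") "max" else "min"
  weight_rule <- match.arg(weight_rule, c("max", "mean", "min"))
  combiner <- switch(weight_rule, max = max, mean = mean, min = min)

  tags <- vapply(networks, .source_tag, "")
  node_tabs <- lapply(networks, network_nodes)
  edge_tabs <- lapply(networks, .edge_table)

  all_nodes <- sort(unique(unlist(lapply(node_tabs, `[[`, "term"))))
  all_keys <- sort(unique(unlist(lapply(edge_tabs, `[[`, "key"))))
  node_in <- vapply(node_tabs, function(t) all_nodes %in% t$term,
                    logical(length(all_nodes)))
  edge_in <- vapply(edge_tabs, function(t) all_keys %in% t$key,
                    logical(length(all_keys)))
  node_in <- matrix(node_in, nrow = length(all_nodes))
  edge_in <- matrix(edge_in, nrow = length(all_keys))

  keep_nodes <- if (mode == "union") rowSums(node_in) > 0 else
    rowSums(node_in) == length(networks)
  keep_edges <- if (mode == "union") rowSums(edge_in) > 0 else
    rowSums(edge_in) == length(networks)
  nodes <- all_nodes[keep_nodes]
  keys <- all_keys[keep_edges]

  freq <- vapply(nodes, function(nd) {
    sum(vapply(node_tabs, function(t) {
      i <- match(nd, t$term)
      if (is.na(i)) 0 else t$frequency[i]
    }, 0))
  }, 0)

  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  g <- igraph::set_vertex_attr(g, "frequency", value = as.numeric(freq))
  if (length(keys)) {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    wts <- numeric(length(keys))
    srcs <- character(length(keys))
    for (i in seq_along(keys)) {
      present <- which(vapply(edge_tabs, function(t) keys[i] %in% t$key, TRUE))
      w <- vapply(present, function(j) {
        t <- edge_tabs[[j]]; t$weight[match(keys[i], t$key)]
      }, 0)
      wts[i] <- combiner(w)
      srcs[i] <- paste(tags[present], collapse = ",")
    }
    g <- igraph::add_edges(g, rbind(vapply(parts, `[`, "", 1L),
                                    vapply(parts, `[`, "", 2L)),
                           weight = wts, sources = srcs)
  }
  out <- .new_word_network(g, metric = metrics,
                           threshold = min(vapply(networks, function(n)
                             as.numeric(n$threshold), 0)),
                           sources = tags)
  out$mode <- mode
  out$weight_rule <- weight_rule
  out$input_thresholds <- vapply(networks, function(n) as.numeric(n$threshold), 0)
  out
}

#' Overlap report between two word networks
#'
#' Quantifies how similar the word relationships inferred from two text
#' sources are: shared node and edge counts and the Jaccard index of the
#' node sets and of the edge sets (an edge is identified by its unordered
#' term pair).
#'
#' @param a,b `word_network` objects of the same metric kind.
#' @return A list of class `network_overlap` with fields `n_nodes_a`,
#'   `n_nodes_b`, `n_edges_a`, `n_edges_b`, `shared_nodes`, `shared_edges`,
#'   `node_jaccard`, `edge_jaccard`. Jaccard of two empty sets is defined
#'   as 1 (identical).
#' @export
compare_networks <- function(a, b) {
  stopifnot(inherits(a, "word_network"), inherits(b, "word_network"))
  if (a$metric != b$metric)
    stop("cannot compare networks of different metric kinds: ",
         a$metric, " vs ", b$metric)
  na <- network_nodes(a)$term; nb <- network_nodes(b)$term
  ea <- .edge_table(a)$key; eb <- .edge_table(b)$key
  jac <- function(x, y) {
    u <- length(union(x, y))
    if (u == 0L) 1 else length(intersect(x, y)) / u
  }
  structure(list(n_nodes_a = length(na), n_nodes_b = length(nb),
                 n_edges_a = length(ea), n_edges_b = length(eb),
                 shared_nodes = length(intersect(na, nb)),
                 shared_edges = length(intersect(ea, eb)),
                 node_jaccard = jac(na, nb),
                 edge_jaccard = jac(ea, eb)),
            class = "network_overlap")
}

#' @export
print.network_overlap <- function(x, ...) {
  cat(sprintf(paste0("network_overlap: %d shared nodes (Jaccard %.3f), ",
                     "%d shared edges (Jaccard %.3f)\n"),
              x$shared_nodes, x$node_jaccard, x$shared_edges, x$edge_jaccard))
  invisible(x)
}
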