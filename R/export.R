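## Serialization of networks, dendrograms and wordcloud/barplot data.
## All exports are deterministic byte-for-byte for a fixed input: nodes and
## edges are written in sorted order and JSON keys are emitted sorted.

#' Write a word network as GraphML
#'
#' Node attributes `frequency` and `cluster`, edge attribute `weight`, and
#' the network metadata (metric, threshold, sources, clustering method and
#' seed) are stored as GraphML attributes, so [read_graphml()] round-trips
#' the network losslessly.
#'
#' @param network A `word_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
to_graphml <- function(network, path) {
  stopifnot(inherits(network, "word_network"))
  g <- network$graph
  perm <- order(igraph::V(g)$name, method = "radix")
  g <- igraph::permute(g, order(perm))
  if (!"cluster" %in% igraph::vertex_attr_names(g))
    g <- igraph::set_vertex_attr(g, "cluster", value = rep(NA_real_, igraph::vcount(g)))
  g <- igraph::set_vertex_attr(g, "cluster",
                               value = as.numeric(igraph::vertex_attr(g, "cluster")))
  g <- igraph::set_graph_attr(g, "metric", network$metric)
  g <- igraph::set_graph_attr(g, "threshold", as.numeric(network$threshold))
  g <- igraph::set_graph_attr(g, "sources", paste(network$sources, collapse = ","))
  if (!is.null(network$cluster_method)) {
    g <- igraph::set_graph_attr(g, "cluster_method", network$cluster_method)
    g <- igraph::set_graph_attr(g, "cluster_seed", as.numeric(network$cluster_seed))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a word network from GraphML written by [to_graphml()]
#' @param path Path to the GraphML file.
#' @return A `word_network`.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  g <- igraph::read_graph(path, format = "graphml")
  ga <- igraph::graph_attr(g)
  cl <- if ("cluster" %in% igraph::vertex_attr_names(g)) {
    v <- igraph::vertex_attr(g, "cluster")
    if (all(is.na(v) | is.nan(v))) NULL else as.integer(v)
  } else NULL
  if (is.null(cl)) {
    g <- igraph::delete_vertex_attr(g, "cluster")
  } else {
    g <- igraph::set_vertex_attr(g, "cluster", value = cl)
  }
  for (a in c("metric", "threshold", "sources", "cluster_method", "cluster_seed"))
    if (a %in% igraph::graph_attr_names(g)) g <- igraph::delete_graph_attr(g, a)
  .new_word_network(
    g,
    metric = if (is.null(ga$metric)) "correlation" else ga$metric,
    threshold = if (is.null(ga$threshold)) -Inf else ga$threshold,
    sources = if (is.null(ga$sources)) "unknown" else
      strsplit(ga$sources, ",", fixed = TRUE)[[1L]],
    cluster_method = ga$cluster_method,
    cluster_seed = if (is.null(ga$cluster_seed)) NULL else as.integer(ga$cluster_seed))
}

# linear rescale to [lo, hi]; constant input maps to the midpoint
.rescale <- function(x, lo, hi) {
  if (length(x) == 0L) return(numeric())
  r <- range(x)
  if (r[1L] == r[2L]) return(rep((lo + hi) / 2, length(x)))
  lo + (x - r[1L]) / (r[2L] - r[1L]) * (hi - lo)
}

#' Export a word network as Cytoscape.js JSON
#'
#' Writes the standard Cytoscape.js `elements` structure: `nodes` with
#' `data.id`, `data.frequency`, `data.cluster` and a `data.size` styling
#' field proportional to frequency (rescaled to 20-60 px), and `edges` with
#' `data.source`, `data.target`, `data.weight` and a `data.width` styling
#' field proportional to weight (rescaled to 1-8 px). Nodes are sorted by
#' id and edges by (source, target); JSON keys are sorted, so output is
#' byte-stable.
#'
#' @param network A `word_network`.
#' @param path Output path (conventionally `.cyjs`).
#' @return The element list, invisibly.
#' @export
to_cyjs <- function(network, path) {
  stopifnot(inherits(network, "word_network"))
  nd <- network_nodes(network)
  nd <- nd[order(nd$term, method = "radix"), , drop = FALSE]
  ed <- network_edges(network)
  sizes <- .rescale(nd$frequency, 20, 60)
  widths <- .rescale(ed$weight, 1, 8)
  nodes <- lapply(seq_len(nrow(nd)), function(i) {
    list(data = list(cluster = if (is.na(nd$cluster[i])) NULL else nd$cluster[i],
                     frequency = nd$frequency[i],
                     id = nd$term[i],
                     size = sizes[i]))
  })
  edges <- lapply(seq_len(nrow(ed)), function(i) {
    list(data = list(source = ed$from[i],
                     target = ed$to[i],
                     weight = ed$weight[i],
                     width = widths[i]))
  })
  out <- list(data = list(metric = network$metric,
                          sources = paste(network$sources, collapse = ","),
                          threshold = as.numeric(network$threshold)),
              elements = list(edges = edges, nodes = nodes))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(out)
}

#' Serialize a cluster tagging as a Newick dendrogram
#'
#' The base dendrogram is written in Newick format with branch lengths
#' equal to merge-height differences and internal node labels carrying the
#' bootstrap probabilities at 2-decimal precision, the convention used for
#' bootstrap support on phylogenies.
#'
#' @param tagging A `cluster_tagging` object.
#' @param path Output path, or `NULL` to return the string only.
#' @return The Newick string, invisibly.
#' @export
to_newick <- function(tagging, path = NULL) {
  stopifnot(inherits(tagging, "cluster_tagging"))
  phy <- ape::as.phylo(tagging$hclust)
  # as.phylo.hclust halves merge heights; rescale so branch lengths are
  # merge-height differences
  phy$edge.length <- phy$edge.length * 2
  keys <- .subtree_keys(tagging$hclust)$keys
  parts <- ape::prop.part(phy)
  labels <- vapply(seq_along(parts), function(i) {
    key <- .set_key(phy$tip.label[parts[[i]]])
    j <- match(key, keys)
    if (is.na(j)) "" else sprintf("%.2f", tagging$bp[j])
  }, "")
  phy$node.label <- labels
  nwk <- ape::write.tree(phy)
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(nwk, con, useBytes = TRUE)
  }
  invisible(nwk)
}

#' Wordcloud / barplot data: top terms by a size metric
#'
#' Returns the top `k` terms with their size, descending, ties broken
#' lexicographically — the data behind a wordcloud or frequency bar plot.
#' For a `term_document_matrix` the size is the total corpus count of the
#' term; for a `word_network` it is the node `frequency` attribute, or the
#' weighted degree with `metric = "degree"`.
#'
#' @param x A `term_document_matrix` or `word_network`.
#' @param k Number of terms, at least 1.
#' @param metric For networks: `"frequency"` (default) or `"degree"`.
#' @return data.frame with columns `term` and `size`.
#' @export
wordcloud_data <- function(x, k = 30L, metric = "frequency") {
  if (length(k) != 1L || is.na(k) || k < 1) stop("k must be an integer >= 1")
  if (inherits(x, "term_document_matrix")) {
    terms <- names(x$term_frequency)
    size <- as.numeric(x$term_frequency)
  } else if (inherits(x, "word_network")) {
    iw <- important_words(x, k = igraph::vcount(x$graph), criterion = metric)
    terms <- iw$term
    size <- iw$weight
  } else {
    stop("x must be a term_document_matrix or a word_network")
  }
  ord <- order(-size, terms, method = "radix")
  utils::head(data.frame(term = terms[ord], size = size[ord],
                         stringsAsFactors = FALSE), as.integer(k))
}

#' Annotate an external cluster graph with wordcloud data
#'
#' For workflows where nodes are clusters of entities (co-expression
#' modules, single-cell clusters, ...) and edges their inferred
#' relationships, each cluster node is annotated with the top-`k` wordcloud
#' terms of its own description corpus, and the result is exported as
#' Cytoscape.js JSON. Edge attributes of the input graph pass through
#' unchanged.
#'
#' @param cluster_graph An `igraph` graph whose vertex names are cluster
#'   ids.
#' @param cluster_corpora Named list mapping every cluster id to a
#'   `corpus` of the descriptions of its members.
#' @param k Number of wordcloud terms per cluster.
#' @param path Output path, or `NULL` to return the structure only.
#' @return The Cytoscape.js element list, invisibly.
#' @export
annotate_cluster_graph <- function(cluster_graph, cluster_corpora, k = 10L,
                                   path = NULL) {
  stopifnot(inherits(cluster_graph, "igraph"))
  ids <- igraph::V(cluster_graph)$name
  if (is.null(ids)) stop("cluster_graph vertices must be named")
  missing <- setdiff(ids, names(cluster_corpora))
  if (length(missing))
    stop(sprintf("no corpus supplied for cluster(s): %s",
                 paste(missing, collapse = ", ")))
  ord <- order(ids, method = "radix")
  nodes <- lapply(ord, function(i) {
    co <- cluster_corpora[[ids[i]]]
    stopifnot(inherits(co, "corpus"))
    tdm <- build_tdm(co, filter_vocabulary(co), scheme = "freq")
    wc <- wordcloud_data(tdm, k = k)
    list(data = list(id = ids[i],
                     n_entities = length(co),
                     words = lapply(seq_len(nrow(wc)), function(j)
                       list(size = wc$size[j], term = wc$term[j]))))
  })
  eattr <- igraph::edge_attr_names(cluster_graph)
  el <- igraph::as_edgelist(cluster_graph)
  edges <- lapply(seq_len(nrow(el)), function(i) {
    data <- list(source = el[i, 1L], target = el[i, 2L])
    for (a in sort(eattr)) data[[a]] <- igraph::edge_attr(cluster_graph, a)[i]
    list(data = data[order(names(data))])
  })
  if (length(edges) > 1L) {
    ek <- vapply(edges, function(e) paste(e$data$source, e$data$target), "")
    edges <- edges[order(ek, method = "radix")]
  }
  out <- list(elements = list(edges = edges, nodes = nodes))
  if (!is.null(path))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(out)
}

#' Write an overlap report as JSON
#' @param overlap A `network_overlap` object from [compare_networks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_overlap <- function(overlap, path) {
  stopifnot(inherits(overlap, "network_overlap"))
  x <- unclass(overlap)
  jsonlite::write_json(x[order(names(x))], path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
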