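random_network <- function(seed = 61, cluster = TRUE) {
  co <- make_random_corpus(8, 14, seed = seed)
  net <- cooccurrence_network(co, filter_vocabulary(co), threshold = 1)
  if (cluster) net <- community_detect(net, seed = 5)
  net
}

test_that("GraphML round-trips nodes, edges, attributes, and metadata", {
  net <- random_network()
  path <- withr::local_tempfile(fileext = ".graphml")
  to_graphml(net, path)
  back <- read_graphml(path)
  expect_identical(network_nodes(back), network_nodes(net))
  e1 <- network_edges(net); e2 <- network_edges(back)
  expect_identical(e1$from, e2$from)
  expect_identical(e1$to, e2$to)
  expect_equal(e1$weight, e2$weight, tolerance = 1e-12)
  expect_identical(back$metric, net$metric)
  expect_equal(back$threshold, net$threshold)
  expect_identical(back$sources, net$sources)
  expect_identical(back$cluster_method, net$cluster_method)
})

test_that("an empty network still writes valid GraphML", {
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = character())
  g <- igraph::set_vertex_attr(g, "frequency", value = numeric())
  net <- structure(list(graph = g, metric = "cooccurrence", threshold = 1,
                        sources = "empty"), class = "word_network")
  path <- withr::local_tempfile(fileext = ".graphml")
  to_graphml(net, path)
  back <- read_graphml(path)
  expect_equal(nrow(network_nodes(back)), 0L)
  expect_equal(nrow(network_edges(back)), 0L)
})

test_that("Cytoscape.js JSON has consistent elements with styling fields", {
  net <- random_network()
  path <- withr::local_tempfile(fileext = ".cyjs")
  to_cyjs(net, path)
  doc <- jsonlite::read_json(path)
  nodes <- doc$elements$nodes
  edges <- doc$elements$edges
  expect_equal(length(nodes), igraph::vcount(net$graph))
  expect_equal(length(edges), igraph::ecount(net$graph))
  ids <- vapply(nodes, function(n) n$data$id, "")
  # referential integrity: every edge endpoint is a node id
  for (e in edges) {
    expect_true(e$data$source %in% ids)
    expect_true(e$data$target %in% ids)
    expect_true(is.numeric(e$data$weight))
    expect_true(e$data$width >= 1 && e$data$width <= 8)
  }
  for (n in nodes) {
    expect_true(is.numeric(n$data$frequency))
    expect_true(n$data$size >= 20 && n$data$size <= 60)
  }
  # weights and frequencies re-read exactly
  e1 <- network_edges(net)
  got_w <- vapply(edges, function(e) e$data$weight, 0)
  expect_equal(sort(got_w), sort(e1$weight))
  # minimal case: 1 node, 0 edges
  co1 <- corpus(data.frame(entity_id = "A", text = "kinase."))
  n1 <- cooccurrence_network(co1, "kinase")
  doc1 <- to_cyjs(n1, withr::local_tempfile(fileext = ".cyjs"))
  expect_equal(length(doc1$elements$nodes), 1L)
  expect_equal(length(doc1$elements$edges), 0L)
})

test_that("Newick output carries leaves, branch lengths, and 2-decimal BP labels", {
  # 3-leaf dendrogram -> exactly 2 internal nodes
  m <- rbind(a = c(2, 4, 6, 1), b = c(1, 2, 3, 0), c = c(5, 1, 0, 4))
  tg3 <- bootstrap_cluster(make_tdm(m), n_boot = 20, seed = 2)
  nwk3 <- to_newick(tg3)
  phy3 <- ape::read.tree(text = nwk3)
  expect_equal(phy3$Nnode, 2L)
  # larger tree: leaf set and internal labels round-trip
  tdm <- build_tdm(make_random_corpus(8, 10, seed = 67),
                   filter_vocabulary(make_random_corpus(8, 10, seed = 67)),
                   scheme = "freq")
  tg <- bootstrap_cluster(tdm, n_boot = 30, seed = 9)
  path <- withr::local_tempfile(fileext = ".nwk")
  to_newick(tg, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, tg$hclust$labels)
  # every parsed internal label equals a base-tree BP at 2 decimals
  labs <- as.numeric(phy$node.label)
  expect_true(all(!is.na(labs)))
  expect_true(all(sprintf("%.2f", labs) %in% sprintf("%.2f", tg$bp)))
  # the root label is 1.00
  parts <- ape::prop.part(phy)
  root_i <- which(lengths(parts) == length(phy$tip.label))
  expect_equal(labs[root_i], 1)
  # branch lengths are merge-height differences: max depth = root height
  depths <- ape::node.depth.edgelength(phy)
  expect_equal(max(depths[seq_along(phy$tip.label)]),
               max(tg$hclust$height), tolerance = 1e-9)
})

test_that("wordcloud data is the top-k frequency table", {
  co <- corpus(data.frame(entity_id = "A", text = "kinase kinase binds."))
  wc <- wordcloud_data(build_tdm(co, filter_vocabulary(co), "freq"), k = 1)
  expect_identical(wc$term, "kinase")
  expect_equal(wc$size, 2)
  co2 <- make_random_corpus(6, 12, seed = 71)
  tdm2 <- build_tdm(co2, filter_vocabulary(co2), "freq")
  wc2 <- wordcloud_data(tdm2, k = 8)
  expect_true(all(diff(wc2$size) <= 0))
  for (i in seq_len(nrow(wc2))) {
    expect_equal(wc2$size[i],
                 sum(vapply(seq_along(co2$documents), function(d)
                   oracle_term_count(co2, wc2$term[i], d), 0L)))
  }
  # network variant agrees with important_words ordering
  net <- random_network(seed = 71)
  expect_identical(wordcloud_data(net, k = 5)$term,
                   important_words(net, k = 5, criterion = "frequency")$term)
})

test_that("cluster-graph annotation attaches per-cluster wordclouds", {
  c1 <- corpus(data.frame(entity_id = c("g1", "g2"),
                          text = c("kinase binds substrate.",
                                   "kinase regulates growth.")))
  c2 <- corpus(data.frame(entity_id = c("g3", "g4"),
                          text = c("membrane transport channel.",
                                   "membrane lipid bilayer.")))
  g <- igraph::make_graph(~ M1 - M2)
  g <- igraph::set_edge_attr(g, "strength", value = 0.731)
  out <- annotate_cluster_graph(g, list(M1 = c1, M2 = c2), k = 3)
  expect_equal(length(out$elements$nodes), 2L)
  expect_equal(length(out$elements$edges), 1L)
  # edge attributes pass through bit-identical
  expect_identical(out$elements$edges[[1]]$data$strength, 0.731)
  # per-node word lists equal an independent per-cluster wordcloud run
  for (node in out$elements$nodes) {
    co <- list(M1 = c1, M2 = c2)[[node$data$id]]
    wc <- wordcloud_data(build_tdm(co, filter_vocabulary(co), "freq"), k = 3)
    expect_identical(vapply(node$data$words, function(w) w$term, ""), wc$term)
    expect_equal(vapply(node$data$words, function(w) w$size, 0), wc$size)
  }
  expect_error(annotate_cluster_graph(g, list(M1 = c1), k = 3), "M2")
})

test_that("exports are byte-identical across repeated runs", {
  net <- random_network()
  f1 <- withr::local_tempfile(fileext = ".cyjs")
  f2 <- withr::local_tempfile(fileext = ".cyjs")
  to_cyjs(net, f1); to_cyjs(net, f2)
  expect_identical(readLines(f1), readLines(f2))
  g1 <- withr::local_tempfile(fileext = ".graphml")
  g2 <- withr::local_tempfile(fileext = ".graphml")
  to_graphml(net, g1); to_graphml(net, g2)
  expect_identical(readLines(g1), readLines(g2))
})
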