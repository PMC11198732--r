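## Bootstrap tagging of word clusters: hierarchical clustering of terms with
## per-cluster bootstrap support, in the style of pvclust. Plain bootstrap
## probabilities (BP) are reported: the fraction of document resamples in
## which a cluster's exact leaf set reappears as a subtree. The multiscale
## approximately-unbiased (AU) correction is deliberately not implemented.

# 1 - correlation distance between term rows; zero-variance terms (possible
# under a degenerate resample) get the maximum distance 2
.term_dist <- function(W, method = "pearson") {
  C <- suppressWarnings(stats::cor(t(W), method = method))
  D <- 1 - C
  D[is.na(D)] <- 2
  diag(D) <- 0
  stats::as.dist(D)
}

# canonical key for a set of terms
.set_key <- function(terms) paste(sort(terms), collapse = "\r")

# leaf sets of every internal node of an hclust tree, as canonical keys
.subtree_keys <- function(hc) {
  labels <- hc$labels
  n <- length(labels)
  sets <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    members <- character()
    for (j in 1:2) {
      m <- hc$merge[i, j]
      members <- c(members, if (m < 0) labels[-m] else sets[[m]])
    }
    sets[[i]] <- members
  }
  list(sets = sets, keys = vapply(sets, .set_key, ""))
}

#' Tag word clusters by bootstrapped hierarchical clustering
#'
#' Builds a base dendrogram of the terms by average-linkage hierarchical
#' clustering on the distance 1 - correlation of term profiles across
#' documents, then resamples the documents (columns) with replacement
#' `n_boot` times, reclusters each resample, and records for every internal
#' node of the base tree whether its exact leaf set reappears as a subtree.
#' The bootstrap probability (BP) of a cluster is the fraction of resamples
#' containing it; clusters with BP at or above `support_threshold` are
#' reported as tagged. The root always has BP 1.
#'
#' @param tdm A `term_document_matrix` with at least 3 terms and 2
#'   documents.
#' @param n_boot Number of bootstrap resamples, at least 1.
#' @param support_threshold BP cutoff in \[0, 1\] for reporting a tagged
#'   cluster.
#' @param seed Integer RNG seed; identical inputs and seed give identical
#'   taggings.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param cor_method Correlation measure for the distance.
#' @return An object of class `cluster_tagging`: list with the base
#'   `hclust` tree, `bp` (BP per internal node, in merge order), `clusters`
#'   (tagged clusters, each a list of `terms` and `bp`, largest first), and
#'   the `n_boot`, `seed`, `support_threshold` used.
#' @export
bootstrap_cluster <- function(tdm, n_boot = 100L, support_threshold = 0.9,
                              seed = 1L, linkage = "average",
                              cor_method = "pearson") {
  stopifnot(inherits(tdm, "term_document_matrix"))
  W <- tdm$weights
  if (nrow(W) < 3L) stop("need at least 3 terms to cluster")
  if (ncol(W) < 2L) stop("need at least 2 documents to cluster")
  if (length(n_boot) != 1L || is.na(n_boot) || n_boot < 1)
    stop("n_boot must be an integer >= 1")
  n_boot <- as.integer(n_boot)
  stopifnot(support_threshold >= 0, support_threshold <= 1)

  base_hc <- stats::hclust(.term_dist(W, cor_method), method = linkage)
  base <- .subtree_keys(base_hc)
  hits <- integer(length(base$keys))

  .with_seed(seed, function() {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(ncol(W), ncol(W), replace = TRUE)
      hc_b <- stats::hclust(.term_dist(W[, idx, drop = FALSE], cor_method),
                            method = linkage)
      keys_b <- .subtree_keys(hc_b)$keys
      hits <<- hits + (base$keys %in% keys_b)
    }
  })
  bp <- hits / n_boot

  tagged_idx <- which(bp >= support_threshold)
  sizes <- vapply(base$sets, length, 1L)
  tagged_idx <- tagged_idx[order(-sizes[tagged_idx], tagged_idx)]
  clusters <- lapply(tagged_idx, function(i) {
    list(terms = sort(base$sets[[i]]), bp = bp[i])
  })

  structure(list(hclust = base_hc, bp = bp, clusters = clusters,
                 n_boot = n_boot, seed = as.integer(seed),
                 support_threshold = support_threshold,
                 linkage = linkage, cor_method = cor_method),
            class = "cluster_tagging")
}

#' @export
print.cluster_tagging <- function(x, ...) {
  cat(sprintf("cluster_tagging: %d terms, %d tagged clusters (n_boot=%d, threshold=%.2f)\n",
              length(x$hclust$labels), length(x$clusters), x$n_boot,
              x$support_threshold))
  invisible(x)
}

#' Bootstrap probability of an exact term set
#'
#' Looks up the BP of the given term set among the internal nodes of the
#' base dendrogram; term sets that are not a node of the tree have no
#' defined BP and return `NA`.
#'
#' @param tagging A `cluster_tagging` object.
#' @param terms Character vector of terms.
#' @return BP in \[0, 1\], or `NA` if the set is not a dendrogram node.
#' @export
cluster_support <- function(tagging, terms) {
  stopifnot(inherits(tagging, "cluster_tagging"))
  keys <- .subtree_keys(tagging$hclust)$keys
  i <- match(.set_key(terms), keys)
  if (is.na(i)) NA_real_ else tagging$bp[i]
}
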