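---
title: "Word networks from entity descriptions: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Word networks from entity descriptions: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termnet)
```

# The model

`termnet` treats an entity list — genes, transcripts, microbial taxa —
as a small text corpus: one document per entity, holding its free-text
functional description. The pipeline has five stages, each a module with
its own exported functions.

**1. Tokenization and filtering.** Text is segmented into sentences on
terminal punctuation, then into lowercase word tokens; punctuation is
stripped from token edges but kept inside tokens, so biomedical compounds
like *ubiquitin-protein* survive intact. Digit-only tokens are dropped.
The vocabulary is then filtered: every enabled filter in a
`filter_config()` must pass (conjunction), so filters can be combined
freely. The available filters, with defaults:

| filter | default | unit / meaning |
|---|---|---|
| `stopwords` | empty | terms removed outright; an English list ships with the package (`default_stopwords()`) |
| `min_token_length` | 1 | characters |
| `min_doc_freq` | 0 | documents a term must appear in |
| `max_doc_freq_fraction` | 1 | fraction of documents a term may appear in; the ubiquity filter that removes *protein*-style boilerplate |
| `min_tfidf` | off | term-level TF-IDF score, $\sum_d \mathrm{tf}_{td}\,\ln(N/\mathrm{df}_t)$ |
| `whitelist` | off | restrict to a curated vocabulary (e.g. a Gene-Ontology-derived word list) |
| `top_k_terms` | off | keep the $k$ most frequent survivors |

Document-frequency and TF-IDF thresholds can be evaluated against a
*background* table precomputed from a large reference corpus
(`read_background()` / `compute_background()`) instead of the small query
corpus, which stabilizes the rare-vs-ubiquitous decision.

The surviving vocabulary is ordered by descending total corpus frequency
with lexicographic tie-breaks; the deterministic order makes `top_k_terms`
truncation, and every downstream output, reproducible.

**2. Term-document matrix.** `build_tdm()` produces a terms × documents
matrix of raw counts (`scheme = "freq"`) or TF-IDF weights
(`scheme = "tfidf"`). The TF-IDF form is the simplest standard one —
$\mathrm{tf}_{td}\cdot\ln(N/\mathrm{df}_t)$, natural log, no length
normalization — chosen so that packaged background tables can be
regenerated from first principles. A term occurring in every document
therefore has weight exactly 0.

**3. Word networks.** Two metrics are supported.
*Correlation*: edge weight is the Pearson (optionally Spearman)
correlation of two terms' matrix rows across documents. Note that row-wise
TF-IDF scaling does not change Pearson correlations, so the correlation
network is effectively a function of the count matrix.
*Co-occurrence*: edge weight is the number of sentences, pooled over all
documents, containing both terms at least once; within-sentence
multiplicity deliberately counts once, so a repeated word does not inflate
its own edges. A per-document counting unit is available
(`unit = "document"`) for corpora whose sentence segmentation is
unreliable.

Weights below the user threshold are not stored as zeros but omitted: the
graph is sparse and the downstream semantics are identical. Terms with
zero variance across documents have undefined correlation; they remain in
the graph as isolated nodes so frequency-based outputs (wordclouds,
important words) still see them.

Thresholds are the main tuning knobs. Co-occurrence thresholds are counts
(≥ 1; 2 is a sensible default at the corpus sizes here, removing
singleton coincidences); correlation thresholds live in [−1, 1] with 0.3
as the package default, a conventional "weak correlation" floor.

**4. Cluster structure.** `community_detect()` assigns every node one
cluster label by greedy modularity optimization (default) or label
propagation; both come from igraph. Negative-weight edges — possible in
correlation networks with a negative threshold — are excluded from the
modularity computation, where they are undefined. Among merge steps tied
for maximal modularity the coarsest partition is chosen, so a fully
connected structureless graph collapses to one community instead of an
arbitrary tie-broken split. Label propagation is stochastic; both methods
run under a caller-supplied seed recorded in the network metadata, and the
RNG state of the session is restored afterwards.

`bootstrap_cluster()` tags word *sets* rather than partitions: the base
tree is average-linkage hierarchical clustering on the distance
$d(t,u) = 1 - \rho_{tu}$, and documents (matrix columns) are resampled
with replacement `n_boot` times. The bootstrap probability (BP) of an
internal node is the fraction of resamples in which its exact leaf set
reappears as a subtree; clusters with BP at or above `support_threshold`
(default 0.9) are reported. Plain BP is implemented deliberately — the
multiscale approximately-unbiased (AU) correction is not. BP is exactly
the resample-and-count semantics that the tagging consumes, it is
verifiable against a brute-force recount (and is, in the test suite), and
at the corpus sizes this package targets the AU machinery adds model
assumptions without changing which clusters are tagged. If a term has
zero variance under a degenerate resample, its pairwise distances are set
to the maximum of the $1-\rho$ metric, 2.0, so resampling never errors.

**5. Ranking, merging, export.** Important words are the top-$k$ nodes by
corpus frequency or weighted degree; an entity's score is the weighted
count of important words among its tokens, optionally divided by its token
count. The weighted sum with optional length normalization is the
package's own choice of scoring rule; unit weights reduce it to a plain
occurrence count, which is the identity the tests pin down. Networks from
different text sources merge by union (edge weight: max by default, so a
strong edge is never diluted) or intersection (min, the conservative
choice), with per-edge source provenance; overlap is quantified by node-
and edge-set Jaccard indices. Exports — GraphML, Cytoscape.js JSON,
Newick with 2-decimal BP node labels, wordcloud/barplot TSV — are
byte-deterministic: nodes and edges are written sorted and JSON keys are
emitted in fixed order, so identical inputs give identical files.

# The synthetic corpus generator

Real description corpora cannot be fetched in a reproducible test, so
`generate_corpus()` plants known structure instead. Each of `n_themes`
themes owns a private vocabulary of `words_per_theme` terms;
`entities_per_theme` entities per theme emit `sentences_per_entity`
sentences of `words_per_sentence` tokens, of which a fraction
`noise_fraction` is drawn from a shared background vocabulary and the
rest (without replacement) from the theme vocabulary. Theme words
therefore co-occur within sentences while words of different themes meet
only through the background.

The background emulates the *ubiquitous generic vocabulary* of real
biomedical descriptions — the *protein / gene / expressed* boilerplate
that appears in most entries and that prefiltering exists to remove. It
is accordingly small (8 words by default) and high-document-frequency:
with the default geometry each background word lands in well over half
the documents while theme words are confined to their theme's documents
(at most one third of the corpus for three themes). The ubiquity filter
`max_doc_freq_fraction = 0.5` then separates the two classes exactly, the
same role it plays on real corpora.

Default geometry: 8 tokens per sentence and 5 sentences per entity, i.e.
40-token descriptions, the order of a typical RefSeq summary; noise
fraction 0.2. Token sampling is uniform within vocabularies — no Zipf
tail — which keeps the generator transparent at the cost of realism:
passing recovery tests on these corpora demonstrates the pipeline's
correctness and its behavior under well-separated themes, *not*
performance on real RefSeq text, which has burstier word distributions,
abbreviation-laden sentences, and themes that share vocabulary.
`shared_theme_overlap` and `theme_labels` exist to build harder cases:
overlapping theme vocabularies within a corpus, and pairs of corpora that
share a theme (same label ⇒ same deterministic vocabulary), used to test
network comparison.

At the standard study conditions (3 themes × 15 words × 10 entities,
noise 0.2), the test suite requires community detection on the
co-occurrence network to recover the planted themes with adjusted Rand
index ≥ 0.9 and bootstrap tagging (`n_boot = 100`) to tag each theme
vocabulary with BP ≥ 0.9.

# Numerical and degenerate-input choices

- Correlations are clamped to [−1, 1] to absorb floating-point spill;
  the "weight ≥ threshold" rule is then exact.
- Zero-variance terms: isolated nodes in correlation networks; distance
  2.0 in bootstrap resamples; never an error.
- All orderings (vocabulary, node tables, edge tables, tagged clusters,
  JSON keys) are total: frequency or size first, lexicographic
  tie-breaks. There is no dependence on hash or insertion order.
- Empty documents are retained end-to-end and score 0, so an entity list
  never silently shrinks.
- Jaccard of two empty sets is defined as 1 (a self-comparison of an
  empty network is still an identity).
- `ape::as.phylo()` halves hclust merge heights; the Newick export
  rescales edge lengths so branch lengths are merge-height differences.
- Seeded operations save and restore the session RNG state, so calling
  them does not perturb a user's own random sequences.

# Problem sizes

The shipped tests run the full pipeline at desk scale: corpora of up to
30 documents, vocabularies up to ~75 terms, 50-corpus oracle sweeps for
the co-occurrence count and 100-resample bootstraps, all in well under a
minute. The algorithms are dense-matrix based (`stats::cor`, sentence ×
term incidence crossproducts) and comfortable to a few thousand terms ×
a few thousand documents; beyond that, the term-document matrix should be
prefiltered harder rather than built wider.

# Known limitations

- The sentence splitter is a terminal-punctuation regex with no
  abbreviation dictionary; biomedical abbreviations ("E. coli") split a
  sentence early. This adds noise to sentence-level co-occurrence counts
  but does not affect the correlation metric.
- No stemming or lemmatization: *kinase* and *kinases* are distinct
  terms. This is deliberate (the filters operate on surface forms, and
  curated whitelists are surface-form lists) but inflates vocabularies on
  morphologically rich text.
- Bootstrap probabilities are raw BP, known to be conservative for small
  clusters relative to AU-corrected values; thresholds tuned for pvclust
  AU values do not transfer directly.
- The package ingests local files only. Fetching descriptions from
  RefSeq, PubMed, or microbial signature databases is out of scope by
  design; `read_corpus()` is the seam where such fetchers would plug in.
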