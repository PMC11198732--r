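Package: termnet
Title: Word Networks for Summarizing Textual Descriptions of Biological Entities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summarizes lists of biological entities (genes, microbial taxa)
    through networks of the words in their free-text functional descriptions.
    Builds term-document matrices with frequency or TF-IDF weighting, applies
    combinable vocabulary filters (stopwords, document frequency, TF-IDF,
    whitelists), constructs correlation or sentence-level co-occurrence word
    networks, detects word communities, tags word clusters by bootstrapped
    hierarchical clustering, scores and prioritizes entities by their content
    of important words, merges and compares networks across text sources, and
    exports results as GraphML, Cytoscape.js JSON, Newick dendrograms, and
    wordcloud/barplot tables. A synthetic corpus generator with planted theme
    structure supports fully offline testing, and a command-line front end
    chains the steps into a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
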