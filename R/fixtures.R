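## Synthetic corpus generator with planted theme structure. Each synthetic
## entity belongs to one theme; its sentences draw most tokens from the
## theme's private vocabulary and the rest from a shared background
## vocabulary, so theme words co-occur within sentences while words of
## different themes meet only through background words. Ground truth is
## returned so recovery (community detection, bootstrap tagging) can be
## measured on every pipeline stage without any database access.

#' Specification of a planted-theme synthetic corpus
#'
#' @param n_themes Number of themes (>= 1).
#' @param words_per_theme Size of each theme's vocabulary.
#' @param entities_per_theme Number of entities generated per theme.
#' @param words_per_sentence Tokens per sentence.
#' @param sentences_per_entity Sentences per entity description.
#' @param noise_fraction Fraction of each sentence's tokens drawn from the
#'   shared background vocabulary instead of the theme vocabulary, in
#'   \[0, 1). Theme tokens within a sentence are sampled without
#'   replacement, so `words_per_theme` must be at least
#'   `words_per_sentence * (1 - noise_fraction)` (rounded); otherwise the
#'   spec is infeasible and rejected.
#' @param shared_theme_overlap Fraction in \[0, 1\] of each theme's
#'   vocabulary borrowed from the previous theme, making adjacent theme
#'   vocabularies overlap; 0 keeps them pairwise disjoint.
#' @param n_background_words Size of the shared background vocabulary.
#' @param theme_labels Optional character vector of theme names (default
#'   `theme1`, `theme2`, ...). Theme vocabularies are derived
#'   deterministically from the labels, so two corpora generated with a
#'   common label share that theme's vocabulary.
#' @param seed Integer RNG seed; generation is fully deterministic given
#'   the spec.
#' @return An object of class `theme_spec`.
#' @export
theme_spec <- function(n_themes = 3L, words_per_theme = 15L,
                       entities_per_theme = 10L, words_per_sentence = 8L,
                       sentences_per_entity = 5L, noise_fraction = 0.2,
                       shared_theme_overlap = 0, n_background_words = 8L,
                       theme_labels = NULL, seed = 1L) {
  stopifnot(n_themes >= 1, words_per_theme >= 1, entities_per_theme >= 1,
            words_per_sentence >= 1, sentences_per_entity >= 1,
            noise_fraction >= 0, noise_fraction < 1,
            shared_theme_overlap >= 0, shared_theme_overlap <= 1,
            n_background_words >= 1)
  n_theme_tokens <- round(words_per_sentence * (1 - noise_fraction))
  if (words_per_theme < n_theme_tokens)
    stop(sprintf(paste0("infeasible spec: words_per_theme (%d) < ",
                        "words_per_sentence * (1 - noise_fraction) (%d)"),
                 as.integer(words_per_theme), as.integer(n_theme_tokens)))
  if (is.null(theme_labels)) theme_labels <- paste0("theme", seq_len(n_themes))
  stopifnot(length(theme_labels) == n_themes, !anyDuplicated(theme_labels))
  structure(list(n_themes = as.integer(n_themes),
                 words_per_theme = as.integer(words_per_theme),
                 entities_per_theme = as.integer(entities_per_theme),
                 words_per_sentence = as.integer(words_per_sentence),
                 sentences_per_entity = as.integer(sentences_per_entity),
                 noise_fraction = noise_fraction,
                 shared_theme_overlap = shared_theme_overlap,
                 n_background_words = as.integer(n_background_words),
                 theme_labels = theme_labels,
                 seed = as.integer(seed)),
            class = "theme_spec")
}

#' Generate a synthetic corpus with planted themes
#'
#' See [theme_spec()] for the generative model. Entity ids are
#' `<label>gene<k>`; theme words are `<label>w<j>` and background words
#' `bgw<j>`, all lowercase alphanumeric so tokenization reproduces them
#' exactly.
#'
#' @param spec A `theme_spec` object.
#' @return A list with `corpus` (a `corpus` object), `entity_themes`
#'   (named character vector mapping each entity id to its theme label),
#'   and `theme_words` (named list mapping each theme label to its
#'   vocabulary).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "theme_spec"))
  word_id <- function(prefix, j) sprintf("%sw%02d", prefix, j)
  theme_words <- list()
  for (i in seq_len(spec$n_themes)) {
    lab <- spec$theme_labels[i]
    own <- word_id(lab, seq_len(spec$words_per_theme))
    if (spec$shared_theme_overlap > 0 && i > 1L) {
      n_shared <- floor(spec$shared_theme_overlap * spec$words_per_theme)
      if (n_shared > 0L) {
        prev <- theme_words[[spec$theme_labels[i - 1L]]]
        own <- c(utils::head(prev, n_shared),
                 own[seq_len(spec$words_per_theme - n_shared)])
      }
    }
    theme_words[[lab]] <- own
  }
  background <- word_id("bg", seq_len(spec$n_background_words))
  n_theme_tok <- round(spec$words_per_sentence * (1 - spec$noise_fraction))
  n_noise_tok <- spec$words_per_sentence - n_theme_tok

  rows <- list()
  entity_themes <- character()
  .with_seed(spec$seed, function() {
    for (i in seq_len(spec$n_themes)) {
      lab <- spec$theme_labels[i]
      vocab <- theme_words[[lab]]
      for (k in seq_len(spec$entities_per_theme)) {
        eid <- sprintf("%sgene%02d", lab, k)
        sents <- vapply(seq_len(spec$sentences_per_entity), function(s) {
          toks <- c(sample(vocab, n_theme_tok, replace = FALSE),
                    if (n_noise_tok > 0L)
                      sample(background, n_noise_tok, replace = TRUE))
          paste0(paste(sample(toks, length(toks)), collapse = " "), ".")
        }, "")
        rows[[length(rows) + 1L]] <<- data.frame(
          entity_id = eid, text = paste(sents, collapse = " "),
          stringsAsFactors = FALSE)
        entity_themes[eid] <<- lab
      }
    }
  })
  df <- do.call(rbind, rows)
  list(corpus = corpus(df, source = "synthetic"),
       entity_themes = entity_themes,
       theme_words = theme_words)
}
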