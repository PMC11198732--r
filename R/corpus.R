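#' Construct a corpus of entity descriptions
#'
#' A corpus is an ordered collection of documents, one per biological entity
#' (gene symbol, taxon name, ...), each holding the raw description text and
#' its sentence-segmented, normalized tokens (see [tokenize()]). Entity ids
#' must be unique; insertion order is preserved. Documents with empty text
#' are retained (they tokenize to zero sentences) so that entity lists keep
#' their length through the pipeline and every queried entity receives a
#' score downstream.
#'
#' @param data A data.frame with one row per entity.
#' @param id_column,text_column Names of the identifier and free-text
#'   columns in `data`.
#' @param source A tag recording where the text came from (e.g. `"refseq"`,
#'   `"manual"`).
#' @param created_at Timestamp metadata (never used in computation).
#' @return An object of class `corpus`.
#' @examples
#' corpus(data.frame(entity_id = c("GENE1", "GENE2"),
#'                   text = c("Kinase binds substrate.",
#'                            "Membrane transport protein.")))
#' @export
corpus <- function(data, id_column = "entity_id", text_column = "text",
                   source = "manual", created_at = Sys.time()) {
  stopifnot(is.data.frame(data))
  for (col in c(id_column, text_column)) {
    if (!col %in% names(data))
      stop(sprintf("column '%s' not found in input", col))
  }
  ids <- as.character(data[[id_column]])
  texts <- as.character(data[[text_column]])
  texts[is.na(texts)] <- ""
  if (any(is.na(ids) | !nzchar(ids))) stop("entity ids must be non-empty")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicated entity id(s): %s", paste(unique(dup), collapse = ", ")))
  docs <- lapply(seq_along(ids), function(i) {
    list(entity_id = ids[i], source = source, raw_text = texts[i],
         sentences = tokenize(texts[i]))
  })
  structure(list(documents = docs, source = source, created_at = created_at),
            class = "corpus")
}

#' @export
length.corpus <- function(x) length(x$documents)

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("corpus: %d documents (source=%s)\n", length(x$documents), x$source))
  invisible(x)
}

#' Entity identifiers of a corpus, in document order
#' @param corpus A `corpus` object.
#' @return Character vector of entity ids.
#' @export
entity_ids <- function(corpus) {
  stopifnot(inherits(corpus, "corpus"))
  vapply(corpus$documents, function(d) d$entity_id, "")
}

.check_utf8 <- function(x, path) {
  bad <- !validUTF8(x)
  if (any(bad))
    stop(sprintf("file '%s' contains bytes that are not valid UTF-8", path))
  x
}

#' Read an entity-description corpus from TSV or JSON
#'
#' The TSV dialect has a header row and tab-separated columns; the JSON
#' dialect is an array of objects. Column/key names are configurable. One
#' document is created per row/record, tokenized on read; duplicate entity
#' ids are rejected and row order is preserved. Files must be UTF-8.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"json"`; defaults to the file extension.
#' @param id_column,text_column Column (TSV) or key (JSON) names.
#' @param source Source tag stored on the corpus.
#' @return A `corpus` object.
#' @export
read_corpus <- function(path, format = c("tsv", "json"),
                        id_column = "entity_id", text_column = "text",
                        source = "manual") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (length(format) > 1L) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "json") "json" else "tsv"
  }
  format <- match.arg(format, c("tsv", "json"))
  if (format == "tsv") {
    lines <- .check_utf8(readLines(path, encoding = "UTF-8", warn = FALSE), path)
    if (length(lines) == 0L) stop(sprintf("file is empty: %s", path))
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    for (col in c(id_column, text_column)) {
      if (!col %in% header) stop(sprintf("column '%s' not found in %s", col, path))
    }
    body <- lines[-1L]
    body <- body[nzchar(body)]
    cells <- lapply(body, function(l) strsplit(l, "\t", fixed = TRUE)[[1L]])
    pick <- function(cell, j) if (j <= length(cell)) cell[j] else ""
    df <- data.frame(
      id = vapply(cells, pick, "", j = match(id_column, header)),
      text = vapply(cells, pick, "", j = match(text_column, header)),
      stringsAsFactors = FALSE)
    names(df) <- c(id_column, text_column)
  } else {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (!is.list(recs)) stop(sprintf("expected a JSON array of objects in %s", path))
    get_key <- function(r, key) {
      if (!key %in% names(r)) stop(sprintf("key '%s' not found in %s", key, path))
      v <- r[[key]]
      if (is.null(v)) "" else as.character(v)
    }
    df <- data.frame(
      id = vapply(recs, get_key, "", key = id_column),
      text = vapply(recs, get_key, "", key = text_column),
      stringsAsFactors = FALSE)
    names(df) <- c(id_column, text_column)
  }
  corpus(df, id_column = id_column, text_column = text_column, source = source)
}

#' Write a corpus to TSV or JSON
#'
#' Round-trips exactly with [read_corpus()]: entity ids, raw text, and
#' document order are preserved. Timestamp metadata is not serialized.
#'
#' @param corpus A `corpus` object.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`; defaults to the file extension.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("tsv", "json")) {
  stopifnot(inherits(corpus, "corpus"))
  if (length(format) > 1L) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "json") "json" else "tsv"
  }
  format <- match.arg(format, c("tsv", "json"))
  ids <- entity_ids(corpus)
  texts <- vapply(corpus$documents, function(d) d$raw_text, "")
  if (format == "tsv") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(c("entity_id\ttext",
                 paste(ids, gsub("[\t\n]", " ", texts), sep = "\t")),
               con, useBytes = TRUE)
  } else {
    recs <- lapply(seq_along(ids), function(i) {
      list(entity_id = ids[i], source = corpus$source, text = texts[i])
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a background word-statistics table
#'
#' Background tables carry document frequencies (and optionally TF-IDF
#' scores) precomputed from a large reference corpus, e.g. all RefSeq
#' summaries, so that rare-vs-ubiquitous decisions need not rely on the
#' small query corpus. Format: TSV with two or three columns (term,
#' doc_freq[, tfidf]), plus a comment line `# n_documents=<N>` recording the
#' reference corpus size. Lines starting with `#` are otherwise ignored.
#'
#' @param path Path to the table.
#' @return An object of class `background_stats`: list with named numeric
#'   `doc_freq`, named numeric `tfidf` (possibly empty), and `n_documents`.
#' @export
read_background <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- .check_utf8(readLines(path, encoding = "UTF-8", warn = FALSE), path)
  n_documents <- 0L
  hdr <- grep("^#\\s*n_documents=", lines, value = TRUE)
  if (length(hdr))
    n_documents <- as.integer(sub("^#\\s*n_documents=\\s*", "", hdr[1L]))
  body_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  doc_freq <- numeric()
  tfidf <- numeric()
  for (i in body_idx) {
    cells <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (tolower(cells[1L]) %in% c("term", "word")) next  # optional header row
    if (length(cells) < 2L)
      stop(sprintf("line %d of %s: expected at least 2 tab-separated columns", i, path))
    dfv <- suppressWarnings(as.numeric(cells[2L]))
    if (is.na(dfv) || dfv < 0)
      stop(sprintf("line %d of %s: document frequency must be a non-negative number", i, path))
    if (n_documents > 0 && dfv > n_documents)
      stop(sprintf("line %d of %s: document frequency exceeds n_documents", i, path))
    doc_freq[cells[1L]] <- dfv
    if (length(cells) >= 3L && nzchar(cells[3L])) {
      tv <- suppressWarnings(as.numeric(cells[3L]))
      if (is.na(tv) || tv < 0)
        stop(sprintf("line %d of %s: tfidf must be a non-negative number", i, path))
      tfidf[cells[1L]] <- tv
    }
  }
  structure(list(doc_freq = doc_freq, tfidf = tfidf,
                 n_documents = n_documents),
            class = "background_stats")
}

#' Write a background word-statistics table
#' @param background A `background_stats` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_background <- function(background, path) {
  stopifnot(inherits(background, "background_stats"))
  terms <- names(background$doc_freq)
  has_tfidf <- length(background$tfidf) > 0L
  rows <- vapply(terms, function(t) {
    if (has_tfidf) {
      tv <- if (t %in% names(background$tfidf)) background$tfidf[[t]] else 0
      sprintf("%s\t%.10g\t%.10g", t, background$doc_freq[[t]], tv)
    } else {
      sprintf("%s\t%.10g", t, background$doc_freq[[t]])
    }
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# n_documents=%d", background$n_documents), rows),
             con, useBytes = TRUE)
  invisible(path)
}

#' Compute background statistics from a reference corpus
#'
#' Produces the document-frequency and term-level TF-IDF maps that
#' [read_background()] reads, so packaged tables can be regenerated. The
#' term-level TF-IDF score is the sum over documents of tf * ln(N/df).
#'
#' @param corpus A `corpus` object.
#' @return A `background_stats` object.
#' @export
compute_background <- function(corpus) {
  stopifnot(inherits(corpus, "corpus"))
  cm <- .count_matrix(corpus)
  n <- ncol(cm)
  df <- rowSums(cm > 0)
  tf <- rowSums(cm)
  score <- ifelse(df > 0, tf * log(n / df), 0)
  structure(list(doc_freq = stats::setNames(as.numeric(df), rownames(cm)),
                 tfidf = stats::setNames(as.numeric(score), rownames(cm)),
                 n_documents = n),
            class = "background_stats")
}

#' Read a vocabulary or stopword list
#'
#' One term per line; lines starting with `#` and blank lines are ignored;
#' terms are lowercased and deduplicated (set semantics).
#'
#' @param path Path to the list file.
#' @return Character vector of normalized terms.
#' @export
read_vocabulary <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- .check_utf8(readLines(path, encoding = "UTF-8", warn = FALSE), path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  unique(tolower(lines))
}
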