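#' Build an inverted index over a corpus
#'
#' Indexes the catch-all text of every record: term postings with
#' within-document term frequencies, document lengths (token counts of the
#' catch-all field), document frequencies and collection statistics — the
#' sufficient statistics for BM25 scoring.
#'
#' @param corpus A `Corpus` from [loadCorpus()], non-empty.
#' @return An `InvertedIndex`: list with `postings` (term -> named integer
#'   vector doc_id -> tf), `df` (term -> document frequency), `doc_len`
#'   (doc_id -> token count), `avg_len`, `n_docs`, `doc_ids`.
#' @export
buildIndex <- function(corpus) {
  stopifnot(inherits(corpus, "Corpus"), length(corpus$records) > 0L)
  ids <- vapply(corpus$records, `[[`, character(1), "doc_id")
  toks <- lapply(corpus$records, function(r) tokenize(r$catchall))
  doc_len <- vapply(toks, length, integer(1))
  names(doc_len) <- ids

  # long (term, doc) pairs -> per-doc term counts -> postings per term
  term <- unlist(toks, use.names = FALSE)
  doc <- rep(ids, doc_len)
  postings <- list()
  if (length(term)) {
    key <- split(doc, term)
    postings <- lapply(key, function(docs) {
      tf <- table(docs)
      out <- as.integer(tf)
      names(out) <- names(tf)
      out
    })
  }
  idx <- list(postings = postings,
              df = vapply(postings, length, integer(1)),
              doc_len = doc_len,
              avg_len = if (length(doc_len)) mean(doc_len) else 0,
              n_docs = length(ids),
              doc_ids = ids)
  class(idx) <- "InvertedIndex"
  idx
}

#' @export
print.InvertedIndex <- function(x, ...) {
  cat("<InvertedIndex> ", x$n_docs, " docs, ", length(x$postings),
      " terms, avg doc length ", format(round(x$avg_len, 2)), "\n", sep = "")
  invisible(x)
}

#' Persist an inverted index as a portable JSON archive
#'
#' The archive is a single JSON object with members `postings` (term ->
#' {doc_id: tf}), `doc_len`, and `stats` ({n_docs, avg_len}), so indexing
#' and searching can run as separate command-line steps.
#'
#' @param index An `InvertedIndex`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
saveIndex <- function(index, path) {
  stopifnot(inherits(index, "InvertedIndex"))
  obj <- list(
    postings = lapply(index$postings, as.list),
    doc_len = as.list(index$doc_len),
    stats = list(n_docs = index$n_docs, avg_len = index$avg_len)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an inverted index from a JSON archive
#'
#' @param path Archive written by [saveIndex()].
#' @return An `InvertedIndex`.
#' @export
loadIndex <- function(path) {
  if (!file.exists(path)) stop("index archive not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  postings <- lapply(obj$postings, function(p) {
    out <- vapply(p, function(v) as.integer(v), integer(1))
    out
  })
  doc_len <- vapply(obj$doc_len, function(v) as.integer(v), integer(1))
  idx <- list(postings = postings,
              df = vapply(postings, length, integer(1)),
              doc_len = doc_len,
              avg_len = as.numeric(obj$stats$avg_len),
              n_docs = as.integer(obj$stats$n_docs),
              doc_ids = names(doc_len))
  class(idx) <- "InvertedIndex"
  idx
}
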