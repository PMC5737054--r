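#' BM25 score of one document for a token bag
#'
#' Okapi BM25 with the defaults of a stock version-5 Lucene/Elasticsearch
#' engine: `k1 = 1.2`, `b = 0.75`, and the non-negative smoothed inverse
#' document frequency `idf(t) = ln(1 + (N - df + 0.5) / (df + 0.5))`.
#' The score is `sum over t in bag of idf(t) * tf * (k1 + 1) /
#' (tf + k1 * (1 - b + b * len / avg_len))`; duplicate bag tokens
#' contribute once per occurrence, and terms absent from the collection
#' contribute zero.
#'
#' @param index An `InvertedIndex`.
#' @param bag Character vector of query tokens (a bag: duplicates count).
#' @param doc_id Document identifier; must be in the index.
#' @param k1,b BM25 shape parameters.
#' @return Non-negative numeric score.
#' @export
bm25Score <- function(index, bag, doc_id, k1 = 1.2, b = 0.75) {
  if (!(doc_id %in% names(index$doc_len)))
    stop("unknown doc_id: ", doc_id)
  if (!length(bag)) return(0)
  len <- index$doc_len[[doc_id]]
  norm <- k1 * (1 - b + b * len / index$avg_len)
  s <- 0
  for (t in bag) {
    post <- index$postings[[t]]
    if (is.null(post)) next
    tf <- unname(post[doc_id])
    if (is.na(tf)) next
    idf <- log(1 + (index$n_docs - length(post) + 0.5) / (length(post) + 0.5))
    s <- s + idf * tf * (k1 + 1) / (tf + norm)
  }
  s
}

# Vectorized clause scores: named numeric vector over all docs matching
# at least one bag token. Duplicate bag tokens add one contribution per
# occurrence, matching the summation over the bag.
bm25ClauseScores <- function(index, bag, k1 = 1.2, b = 0.75) {
  if (!length(bag)) return(numeric(0))
  counts <- table(bag)
  scores <- numeric(0)
  for (t in names(counts)) {
    post <- index$postings[[t]]
    if (is.null(post)) next
    df <- length(post)
    idf <- log(1 + (index$n_docs - df + 0.5) / (df + 0.5))
    len <- index$doc_len[names(post)]
    norm <- k1 * (1 - b + b * len / index$avg_len)
    contrib <- counts[[t]] * idf * post * (k1 + 1) / (post + norm)
    hit <- names(post)
    known <- hit %in% names(scores)
    scores[hit[known]] <- scores[hit[known]] + contrib[known]
    scores <- c(scores, contrib[!known])
  }
  scores
}

#' Rank documents for a structured query
#'
#' Both clauses are optional ("should" semantics): a document matching
#' either the baseline or the expansion tokens is a candidate, and its
#' score is `baseline_weight * bm25(baseline) + mesh_weight *
#' bm25(expansion)`. Documents with positive score are sorted by score
#' descending, ties broken by ascending doc_id (a stable rule so run
#' files are byte-identical across runs), and truncated to `top_n`.
#'
#' @param index An `InvertedIndex`.
#' @param query A `StructuredQuery`.
#' @param top_n Maximum results returned (default 1000 per run entry).
#' @return A `RankedList`: data frame with columns `qid`, `doc_id`,
#'   `rank`, `score`; zero rows (with a warning) for an empty query.
#' @export
searchIndex <- function(index, query, top_n = 1000L) {
  stopifnot(inherits(index, "InvertedIndex"),
            inherits(query, "StructuredQuery"), top_n >= 1L)
  empty <- data.frame(qid = character(0), doc_id = character(0),
                      rank = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  attr(empty, "qid") <- query$qid  # zero-row lists keep their identity
  class(empty) <- c("RankedList", "data.frame")
  if (!length(query$baseline_tokens)) {
    warning("query ", query$qid, " has no baseline tokens; empty result")
    return(empty)
  }
  cfg <- query$config
  base <- bm25ClauseScores(index, query$baseline_tokens)
  mesh <- bm25ClauseScores(index, query$expansion_tokens)
  docs <- union(names(base), names(mesh))
  if (!length(docs)) return(empty)
  bs <- unname(base[docs]); bs[is.na(bs)] <- 0
  ms <- unname(mesh[docs]); ms[is.na(ms)] <- 0
  s <- cfg$baseline_weight * bs + cfg$mesh_weight * ms
  names(s) <- docs
  s <- s[s > 0]
  if (!length(s)) return(empty)
  ord <- order(-s, names(s), method = "radix")
  s <- s[ord]
  n <- min(length(s), as.integer(top_n))
  out <- data.frame(qid = rep(query$qid, n),
                    doc_id = names(s)[seq_len(n)],
                    rank = seq_len(n),
                    score = unname(s[seq_len(n)]),
                    stringsAsFactors = FALSE)
  class(out) <- c("RankedList", "data.frame")
  out
}
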