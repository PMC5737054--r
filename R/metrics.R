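#' @name metrics
#' @title Graded-relevance retrieval metrics
#'
#' @description
#' The five challenge metrics over graded judgments (0 = not, 1 =
#' partially, 2 = fully relevant): precision at k in two variants
#' (counting grade >= 1 or only grade 2), NDCG at k, average precision,
#' and the inferred estimators infAP and infNDCG for stratified-sampled
#' judgments. Unjudged documents count as not relevant; every metric lies
#' in [0, 1].
#'
#' Gains are linear in the grade by default (the treceval-family
#' convention); `exponential = TRUE` uses `2^grade - 1`.
NULL

# doc_id -> grade lookup for one query
gradesFor <- function(qrels, qid) {
  rows <- qrels[qrels$qid == qid, , drop = FALSE]
  g <- rows$grade
  names(g) <- rows$doc_id
  g
}

gainOf <- function(grade, exponential = FALSE) {
  if (exponential) 2^grade - 1 else grade
}

rankDiscount <- function(i) 1 / log2(i + 1)

rankedGrades <- function(ranked, gmap) {
  g <- gmap[ranked$doc_id]
  g[is.na(g)] <- 0L
  unname(g)
}

#' Precision at k with a relevance-grade threshold
#'
#' Fraction of the top `k` results with grade at least `min_grade`;
#' unjudged documents count as grade 0 and lists shorter than `k` are
#' conceptually padded with non-relevant documents.
#'
#' @param ranked A `RankedList` for one query.
#' @param qrels A `Qrels`.
#' @param k Cutoff (>= 1); 10 in the challenge reporting.
#' @param min_grade 1 counts partially relevant ("+partial"); 2 requires
#'   fully relevant ("-partial").
#' @return Numeric in [0, 1].
#' @export
precisionAtK <- function(ranked, qrels, k = 10L, min_grade = 1L) {
  stopifnot(k >= 1L, min_grade %in% 1:2)
  if (!nrow(ranked)) return(0)
  g <- rankedGrades(utils::head(ranked, k), gradesFor(qrels, ranked$qid[1]))
  sum(g >= min_grade) / k
}

#' Normalized discounted cumulative gain at k
#'
#' `DCG@k = sum over i <= k of gain(grade_i) / log2(i + 1)` (rank 1
#' undiscounted), normalized by the ideal DCG@k obtained by sorting all of
#' the query's graded documents by grade descending; 0/0 is defined as 0.
#'
#' @inheritParams precisionAtK
#' @param exponential Use `2^grade - 1` gains instead of linear.
#' @return Numeric in [0, 1].
#' @export
ndcgAtK <- function(ranked, qrels, k = 10L, exponential = FALSE) {
  stopifnot(k >= 1L)
  if (!nrow(ranked)) qid <- NULL else qid <- ranked$qid[1]
  gmap <- if (is.null(qid)) integer(0) else gradesFor(qrels, qid)
  ideal <- sort(gmap[gmap > 0], decreasing = TRUE)
  idcg <- dcgOf(gainOf(utils::head(unname(ideal), k), exponential))
  if (idcg == 0) return(0)
  if (!nrow(ranked)) return(0)
  g <- rankedGrades(utils::head(ranked, k), gmap)
  dcgOf(gainOf(g, exponential)) / idcg
}

dcgOf <- function(gains) {
  if (!length(gains)) return(0)
  sum(gains * rankDiscount(seq_along(gains)))
}

#' Average precision with graded judgments binarized at a threshold
#'
#' `AP = (1/R) * sum over relevant retrieved ranks i of (relevant count
#' within top i) / i`, with `R` the query's total number of documents of
#' grade >= `min_grade` (retrieved or not); 0 when `R = 0`.
#'
#' @inheritParams precisionAtK
#' @return Numeric in [0, 1].
#' @export
averagePrecision <- function(ranked, qrels, min_grade = 1L) {
  qid <- if (nrow(ranked)) ranked$qid[1] else NULL
  gmap <- if (is.null(qid)) integer(0) else gradesFor(qrels, qid)
  R <- sum(gmap >= min_grade)
  if (R == 0) return(0)
  if (!nrow(ranked)) return(0)
  rel <- rankedGrades(ranked, gmap) >= min_grade
  hits <- which(rel)
  sum(cumsum(rel)[hits] / hits) / R
}

# Per-query view of SampledQrels: stratum of each pooled doc, rate of
# each stratum, grade of each sampled doc.
sqView <- function(sq, qid) {
  pool <- sq$pool[sq$pool$qid == qid, , drop = FALSE]
  rates <- sq$rates[sq$rates$qid == qid, , drop = FALSE]
  grades <- sq$grades[sq$grades$qid == qid, , drop = FALSE]
  stratum <- pool$stratum
  names(stratum) <- pool$doc_id
  rate <- rates$rate
  names(rate) <- rates$stratum
  g <- grades$grade
  names(g) <- grades$doc_id
  miss <- setdiff(unique(stratum), names(rate))
  if (length(miss))
    stop("pooled stratum without a rate for query ", qid, ": ", miss[1])
  list(stratum = stratum, rate = rate, grade = g,
       census = all(rate == 1) && all(names(stratum) %in% names(g)))
}

sqAsQrels <- function(view, qid) {
  q <- data.frame(qid = rep(qid, length(view$grade)),
                  doc_id = names(view$grade),
                  grade = unname(view$grade), stringsAsFactors = FALSE)
  class(q) <- c("Qrels", "data.frame")
  q
}

#' Inferred average precision over sampled judgments
#'
#' Estimates AP when only a stratified random sample of the judging pool
#' is graded. For each sampled relevant document at rank k the expected
#' precision at k is estimated from the pooled and sampled documents above
#' k, with Lidstone smoothing `eps`; counts above k are weighted by the
#' reciprocal sampling rate of their stratum. When every stratum is
#' sampled at rate 1 and the whole pool is judged, the sample is a census
#' and the estimator reduces to the exact [averagePrecision()] (no
#' smoothing is needed or applied in that case).
#'
#' @param ranked A `RankedList` for one query.
#' @param sq A `SampledQrels`.
#' @param min_grade Relevance binarization threshold (1 or 2).
#' @param eps Smoothing constant for the within-sample precision estimate.
#' @return Numeric estimate (clamped to [0, 1]); 0 when no sampled
#'   relevant documents exist.
#' @export
infAP <- function(ranked, sq, min_grade = 1L, eps = 1e-5) {
  stopifnot(inherits(sq, "SampledQrels"))
  if (!nrow(ranked)) return(0)
  qid <- ranked$qid[1]
  v <- sqView(sq, qid)
  R_s <- sum(v$grade >= min_grade)
  if (R_s == 0) return(0)
  if (v$census)
    return(averagePrecision(ranked, sqAsQrels(v, qid), min_grade))

  docs <- ranked$doc_id
  in_pool <- docs %in% names(v$stratum)
  sampled <- docs %in% names(v$grade)
  grade <- ifelse(sampled, v$grade[docs], NA)
  w <- ifelse(in_pool, 1 / v$rate[v$stratum[docs]], NA)

  total <- 0
  pool_above <- 0L
  rel_w <- 0; nonrel_w <- 0
  for (i in seq_along(docs)) {
    if (sampled[i] && grade[i] >= min_grade) {
      total <- total + if (i == 1L) 1 else {
        1 / i + ((i - 1) / i) * (pool_above / (i - 1)) *
          ((rel_w + eps) / (rel_w + nonrel_w + 2 * eps))
      }
    }
    # update "above" statistics for the next rank
    if (in_pool[i]) pool_above <- pool_above + 1L
    if (sampled[i]) {
      if (grade[i] >= min_grade) rel_w <- rel_w + w[i]
      else nonrel_w <- nonrel_w + w[i]
    }
  }
  min(1, max(0, total / R_s))
}

#' Inferred NDCG over sampled judgments
#'
#' Estimates NDCG over the full ranked list. Within each sampling stratum
#' the number of documents of each grade is estimated as (sampled count
#' of that grade) / rate, and the mean gain of sampled documents stands in
#' for pooled-but-unsampled ones. The estimated DCG sums, over the whole
#' ranked list, the discount `1/log2(i+1)` times: the actual gain for
#' judged documents, the stratum's mean sampled gain for pooled-but-
#' unsampled documents, and 0 outside the pool. The estimated ideal DCG
#' fills ranks with the estimated number of fully relevant documents
#' (gain 2), then partially relevant (gain 1); a fractional estimated
#' count contributes fractionally at the next rank. The ratio is clamped
#' to [0, 1]; an empty ranked list or zero ideal gives 0.
#'
#' @inheritParams infAP
#' @param exponential Use `2^grade - 1` gains.
#' @return Numeric in [0, 1].
#' @export
infNDCG <- function(ranked, sq, exponential = FALSE) {
  stopifnot(inherits(sq, "SampledQrels"))
  if (!nrow(ranked)) return(0)
  qid <- ranked$qid[1]
  v <- sqView(sq, qid)
  strata <- unique(unname(v$stratum))

  # per-stratum estimated grade counts and mean sampled gain
  m_hat <- list()
  g_bar <- numeric(0)
  for (s in strata) {
    docs_s <- names(v$stratum)[v$stratum == s]
    sampled_s <- intersect(docs_s, names(v$grade))
    gs <- unname(v$grade[sampled_s])
    m_hat[[s]] <- c(`1` = sum(gs == 1L), `2` = sum(gs == 2L)) / v$rate[[s]]
    g_bar[[s]] <- if (length(gs)) mean(gainOf(gs, exponential)) else 0
  }

  docs <- ranked$doc_id
  gain <- numeric(length(docs))
  sampled <- docs %in% names(v$grade)
  gain[sampled] <- gainOf(unname(v$grade[docs[sampled]]), exponential)
  unsampled_pooled <- !sampled & docs %in% names(v$stratum)
  gain[unsampled_pooled] <- g_bar[v$stratum[docs[unsampled_pooled]]]
  dcg <- dcgOf(gain)

  n2 <- sum(vapply(m_hat, `[[`, numeric(1), "2"))
  n1 <- sum(vapply(m_hat, `[[`, numeric(1), "1"))
  idcg <- idealFillDCG(c(n2, n1), gainOf(c(2L, 1L), exponential))
  if (idcg == 0) return(0)
  min(1, max(0, dcg / idcg))
}

# Ideal DCG from estimated (possibly fractional) per-gain document counts:
# whole documents occupy successive ranks; a fractional remainder
# contributes remainder * gain * discount at the next rank.
idealFillDCG <- function(counts, gains) {
  r <- 1L
  total <- 0
  for (j in seq_along(counts)) {
    n <- counts[j]
    if (n <= 0) next
    full <- floor(n)
    if (full > 0) {
      total <- total + gains[j] * sum(rankDiscount(seq.int(r, r + full - 1L)))
      r <- r + as.integer(full)
    }
    frac <- n - full
    if (frac > 1e-12) {
      total <- total + frac * gains[j] * rankDiscount(r)
      r <- r + 1L
    }
  }
  total
}
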