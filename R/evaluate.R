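#' Evaluate a run against graded and sampled judgments
#'
#' Computes, per query and as unweighted arithmetic means over evaluated
#' queries, the five challenge metrics: infAP, infNDCG (over the full
#' submitted list), NDCG@k, and P@k counting and not counting partial
#' relevance. Queries in the run but absent from the qrels are excluded
#' from the means with a warning; queries judged but with no relevant
#' documents score zero and are flagged. Duplicate doc_ids within a
#' query's entries are an error.
#'
#' @param run A run data frame (from [readRun()]), a `RankedList`, or a
#'   list of `RankedList`s.
#' @param qrels A `Qrels`.
#' @param sampled_qrels A `SampledQrels`, or `NULL` to treat the qrels as
#'   a fully judged pool (census) for the inferred metrics.
#' @param k Cutoff for NDCG@k and P@k (default 10).
#' @param min_grade_ap Binarization threshold for AP/infAP (default 1:
#'   partial counts as relevant).
#' @param exponential Use `2^grade - 1` gains in the NDCG family.
#' @param eps infAP smoothing constant.
#' @return A `MetricReport`: list with `per_query` (data frame), `means`
#'   (named numeric), `n_excluded`.
#' @export
evaluateRun <- function(run, qrels, sampled_qrels = NULL, k = 10L,
                        min_grade_ap = 1L, exponential = FALSE,
                        eps = 1e-5) {
  lists <- if (inherits(run, "RankedList")) list(run)
  else if (is.data.frame(run)) runToRankedLists(run)
  else run
  for (rl in lists) {
    if (nrow(rl) && anyDuplicated(rl$doc_id))
      stop("duplicate doc_id entries for query ", rl$qid[1])
  }
  if (is.null(sampled_qrels)) sampled_qrels <- censusSampledQrels(qrels)

  judged_qids <- unique(qrels$qid)
  rows <- list(); n_excluded <- 0L
  for (rl in lists) {
    qid <- if (nrow(rl)) rl$qid[1] else attr(rl, "qid")
    if (!nrow(rl)) {
      # an empty result list for a judged query scores zero, flagged
      if (!is.null(qid) && qid %in% judged_qids) {
        warning("query ", qid, " retrieved no documents; scored zero")
        rows[[qid]] <- data.frame(
          qid = qid, infAP = 0, infNDCG = 0, ndcg_at_k = 0,
          p_at_k_partial = 0, p_at_k_full = 0, stringsAsFactors = FALSE)
      }
      next
    }
    if (!qid %in% judged_qids) {
      warning("query ", qid, " absent from qrels; excluded from means")
      n_excluded <- n_excluded + 1L
      next
    }
    rows[[qid]] <- data.frame(
      qid = qid,
      infAP = infAP(rl, sampled_qrels, min_grade = min_grade_ap, eps = eps),
      infNDCG = infNDCG(rl, sampled_qrels, exponential = exponential),
      ndcg_at_k = ndcgAtK(rl, qrels, k = k, exponential = exponential),
      p_at_k_partial = precisionAtK(rl, qrels, k = k, min_grade = 1L),
      p_at_k_full = precisionAtK(rl, qrels, k = k, min_grade = 2L),
      stringsAsFactors = FALSE)
  }
  per_query <- if (length(rows)) do.call(rbind, rows)
  else data.frame(qid = character(0), infAP = numeric(0),
                  infNDCG = numeric(0), ndcg_at_k = numeric(0),
                  p_at_k_partial = numeric(0), p_at_k_full = numeric(0),
                  stringsAsFactors = FALSE)
  rownames(per_query) <- NULL
  metric_cols <- setdiff(names(per_query), "qid")
  means <- if (nrow(per_query)) colMeans(per_query[metric_cols])
  else stats::setNames(rep(NA_real_, length(metric_cols)), metric_cols)
  structure(list(per_query = per_query, means = means,
                 n_excluded = n_excluded, k = k),
            class = "MetricReport")
}

# Full-information SampledQrels: the qrels are the pool, one stratum,
# rate 1 — under which the inferred metrics equal the exact ones.
censusSampledQrels <- function(qrels) {
  pool <- data.frame(qid = qrels$qid, doc_id = qrels$doc_id,
                     stratum = "1", stringsAsFactors = FALSE)
  rates <- data.frame(qid = unique(qrels$qid), stratum = "1", rate = 1,
                      stringsAsFactors = FALSE)
  grades <- data.frame(qid = qrels$qid, doc_id = qrels$doc_id,
                       grade = qrels$grade, stringsAsFactors = FALSE)
  sampledQrels(pool, rates, grades)
}

#' @export
print.MetricReport <- function(x, ...) {
  cat("<MetricReport> ", nrow(x$per_query), " queries (",
      x$n_excluded, " excluded)\n", sep = "")
  if (nrow(x$per_query)) {
    cat("means:\n")
    print(round(x$means, 4))
  }
  invisible(x)
}

#' Write a metric report as TSV with a machine-readable JSON twin
#'
#' The TSV holds one row per query plus a MEAN row; the JSON twin (same
#' path with extension `.json`, or `json_path`) holds the identical
#' numbers.
#'
#' @param report A `MetricReport`.
#' @param path Output TSV path.
#' @param json_path Optional explicit JSON path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, json_path = NULL) {
  stopifnot(inherits(report, "MetricReport"))
  pq <- report$per_query
  lines <- c(paste(names(pq), collapse = "\t"))
  fmt <- function(v) formatC(v, format = "f", digits = 6)
  for (i in seq_len(nrow(pq)))
    lines <- c(lines, paste(c(pq$qid[i], fmt(as.numeric(pq[i, -1]))),
                            collapse = "\t"))
  lines <- c(lines, paste(c("MEAN", fmt(report$means)), collapse = "\t"))
  writeLines(lines, path)
  if (is.null(json_path))
    json_path <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    list(per_query = pq, means = as.list(report$means),
         n_excluded = report$n_excluded),
    json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
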