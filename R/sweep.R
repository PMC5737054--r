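#' Parameter sweep over term caps and weight ratios
#'
#' Runs retrieval and evaluation for every combination of MeSH term cap
#' and mesh:baseline weight ratio on identically preprocessed queries,
#' alongside a baseline (cap 0) column, and tabulates the best cell per
#' query by infNDCG. Ties prefer the smaller cap, then the heavier
#' baseline weighting (larger baseline/mesh ratio) — the lightest-touch
#' expansion among equals.
#'
#' @param index An `InvertedIndex`.
#' @param queries Data frame `qid`, `text` (from [readQueries()]).
#' @param table A `SynonymTable`.
#' @param Ks Non-empty vector of per-token caps.
#' @param ratios Non-empty character vector of "mesh:baseline" ratios.
#' @param qrels A `Qrels`.
#' @param sampled_qrels Optional `SampledQrels` for the inferred metrics.
#' @param top_n Results per query (default 1000).
#' @param k Cutoff for NDCG@k / P@k.
#' @param stop_list,phrase_patterns Preprocessing fixtures.
#' @param ... Passed to [evaluateRun()].
#' @return A `SweepGrid`: list with `Ks`, `ratios`, `cells` (named list of
#'   `MetricReport`s keyed `"K<K>_<ratio>"`), `baseline` (the cap-0
#'   report), `best_per_query` (data frame `qid`, `K`, `ratio`, `infNDCG`,
#'   `baseline_infNDCG`, `delta`).
#' @export
sweepGrid <- function(index, queries, table, Ks, ratios, qrels,
                      sampled_qrels = NULL, top_n = 1000L, k = 10L,
                      stop_list = loadStopwords(),
                      phrase_patterns = loadPhrasePatterns(), ...) {
  stopifnot(length(Ks) >= 1L, length(ratios) >= 1L)

  runCell <- function(K, ratio) {
    cfg <- expansionConfig(K, ratio)
    lists <- lapply(seq_len(nrow(queries)), function(i) {
      sq <- structuredQuery(queries$qid[i], queries$text[i], table, cfg,
                            stop_list = stop_list,
                            phrase_patterns = phrase_patterns)
      searchIndex(index, sq, top_n = top_n)
    })
    tryCatch(
      evaluateRun(lists, qrels, sampled_qrels, k = k, ...),
      error = function(e)
        stop("sweep cell K=", K, " ratio=", ratio, ": ",
             conditionMessage(e)))
  }

  baseline <- runCell(0L, "1:1")
  cells <- list()
  meta <- list()
  for (K in Ks) for (ratio in ratios) {
    key <- paste0("K", K, "_", ratio)
    cells[[key]] <- runCell(K, ratio)
    w <- parseRatio(ratio)
    meta[[key]] <- list(K = K, ratio = ratio,
                        heaviness = w[["baseline"]] / w[["mesh"]])
  }

  qids <- baseline$per_query$qid
  best <- lapply(qids, function(q) {
    vals <- vapply(names(cells), function(key) {
      pq <- cells[[key]]$per_query
      v <- pq$infNDCG[pq$qid == q]
      if (length(v)) v else NA_real_
    }, numeric(1))
    ord <- order(-vals,
                 vapply(meta, `[[`, numeric(1), "K"),
                 -vapply(meta, `[[`, numeric(1), "heaviness"))
    key <- names(cells)[ord[1]]
    b <- baseline$per_query$infNDCG[baseline$per_query$qid == q]
    data.frame(qid = q, K = meta[[key]]$K, ratio = meta[[key]]$ratio,
               infNDCG = vals[[key]], baseline_infNDCG = b,
               delta = vals[[key]] - b, stringsAsFactors = FALSE)
  })
  best_per_query <- do.call(rbind, best)
  rownames(best_per_query) <- NULL
  structure(list(Ks = Ks, ratios = ratios, cells = cells,
                 baseline = baseline, best_per_query = best_per_query),
            class = "SweepGrid")
}

#' @export
print.SweepGrid <- function(x, ...) {
  cat("<SweepGrid> ", length(x$Ks), " caps x ", length(x$ratios),
      " ratios; mean infNDCG by cell:\n", sep = "")
  for (key in names(x$cells))
    cat("  ", key, ": ",
        formatC(x$cells[[key]]$means[["infNDCG"]], format = "f",
                digits = 4), "\n", sep = "")
  cat("  baseline: ",
      formatC(x$baseline$means[["infNDCG"]], format = "f", digits = 4),
      "\n", sep = "")
  invisible(x)
}
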