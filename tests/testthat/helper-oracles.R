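# Independent, deliberately naive reference implementations of the
# metrics and of BM25 scoring, plus random-instance generators. These
# stay brute-force so they can serve as oracles for the package code.

oracleGrade <- function(qrels, qid, doc_id) {
  g <- qrels$grade[qrels$qid == qid & qrels$doc_id == doc_id]
  if (length(g)) g[1] else 0L
}

oraclePrecisionAtK <- function(ranked, qrels, k, min_grade) {
  hits <- 0L
  for (i in seq_len(min(k, nrow(ranked)))) {
    g <- oracleGrade(qrels, ranked$qid[1], ranked$doc_id[i])
    if (g >= min_grade) hits <- hits + 1L
  }
  hits / k
}

oracleDCG <- function(grades) {
  s <- 0
  for (i in seq_along(grades)) s <- s + grades[i] / log2(i + 1)
  s
}

oracleNdcgAtK <- function(ranked, qrels, k) {
  qid <- ranked$qid[1]
  got <- vapply(seq_len(min(k, nrow(ranked))), function(i)
    oracleGrade(qrels, qid, ranked$doc_id[i]), integer(1))
  all_g <- sort(qrels$grade[qrels$qid == qid], decreasing = TRUE)
  ideal <- head(all_g[all_g > 0], k)
  idcg <- oracleDCG(ideal)
  if (idcg == 0) return(0)
  oracleDCG(got) / idcg
}

oracleAveragePrecision <- function(ranked, qrels, min_grade = 1L) {
  qid <- if (nrow(ranked)) ranked$qid[1] else return(0)
  R <- sum(qrels$grade[qrels$qid == qid] >= min_grade)
  if (R == 0) return(0)
  s <- 0; rel_seen <- 0L
  for (i in seq_len(nrow(ranked))) {
    if (oracleGrade(qrels, qid, ranked$doc_id[i]) >= min_grade) {
      rel_seen <- rel_seen + 1L
      s <- s + rel_seen / i
    }
  }
  s / R
}

# Literal transcription of the smoothed inferred-AP estimator for a
# single uniform sampling rate; sampled_grades is doc_id -> grade over
# the sampled docs, pool_docs the full pool.
oracleInfAP <- function(ranked, pool_docs, sampled_grades, rate,
                        min_grade = 1L, eps = 1e-5) {
  R_s <- sum(sampled_grades >= min_grade)
  if (R_s == 0) return(0)
  total <- 0
  docs <- ranked$doc_id
  for (i in seq_along(docs)) {
    d <- docs[i]
    if (!d %in% names(sampled_grades)) next
    if (sampled_grades[[d]] < min_grade) next
    if (i == 1) { total <- total + 1; next }
    above <- docs[seq_len(i - 1)]
    d_above <- sum(above %in% pool_docs)
    samp_above <- above[above %in% names(sampled_grades)]
    rel <- sum(sampled_grades[samp_above] >= min_grade) / rate
    nonrel <- sum(sampled_grades[samp_above] < min_grade) / rate
    total <- total + 1 / i + ((i - 1) / i) * (d_above / (i - 1)) *
      ((rel + eps) / (rel + nonrel + 2 * eps))
  }
  min(1, max(0, total / R_s))
}

oracleBM25 <- function(doc_tokens_list, bag, doc, k1 = 1.2, b = 0.75) {
  N <- length(doc_tokens_list)
  avg <- mean(vapply(doc_tokens_list, length, integer(1)))
  toks <- doc_tokens_list[[doc]]
  s <- 0
  for (t in bag) {
    df <- sum(vapply(doc_tokens_list, function(x) t %in% x, logical(1)))
    if (df == 0) next
    tf <- sum(toks == t)
    if (tf == 0) next
    idf <- log(1 + (N - df + 0.5) / (df + 0.5))
    s <- s + idf * tf * (k1 + 1) /
      (tf + k1 * (1 - b + b * length(toks) / avg))
  }
  s
}

# ---- random instance generators -------------------------------------

randomRankedList <- function(qid, doc_pool, n) {
  docs <- sample(doc_pool, n)
  rl <- data.frame(qid = rep(qid, n), doc_id = docs, rank = seq_len(n),
                   score = sort(stats::runif(n, 1, 10), decreasing = TRUE),
                   stringsAsFactors = FALSE)
  class(rl) <- c("RankedList", "data.frame")
  rl
}

randomQrels <- function(qid, doc_pool) {
  judged <- sample(doc_pool, max(1L, rbinom(1, length(doc_pool), 0.7)))
  q <- data.frame(qid = rep(qid, length(judged)), doc_id = judged,
                  grade = sample(0:2, length(judged), replace = TRUE),
                  stringsAsFactors = FALSE)
  class(q) <- c("Qrels", "data.frame")
  q
}

# In-memory toy corpus -> Corpus object without touching disk
corpusFromTexts <- function(texts) {
  recs <- lapply(names(texts), function(id)
    flattenRecord(list(text = texts[[id]]), id))
  structure(list(records = recs, n_skipped = 0L), class = "Corpus")
}

# One synthetic replicate: generate, index, run baseline and expanded
# configs, pool + sample, return both mean infNDCGs.
replicateStudy <- function(rho, seed, n_docs = 500L, n_queries = 10L,
                           K = 5L, ratio = "1:5") {
  dir <- tempfile("repl")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  cfg <- synthConfig(n_docs = n_docs, n_queries = n_queries,
                     mismatch_rate = rho, seed = seed)
  out <- generateCollection(cfg, dir, corpus_format = "jsonl")
  idx <- buildIndex(loadCorpus(out$corpus, id_field = "id", quiet = TRUE))
  tab <- loadSynonyms(out$synonyms)
  queries <- readQueries(out$queries)
  qrels <- readQrels(out$qrels)
  mk <- function(cfgE) lapply(seq_len(nrow(queries)), function(i)
    searchIndex(idx, structuredQuery(queries$qid[i], queries$text[i],
                                     tab, cfgE)))
  base <- mk(expansionConfig(0L))
  exp4 <- mk(expansionConfig(K, ratio))
  f1 <- file.path(dir, "base.run"); f2 <- file.path(dir, "exp.run")
  writeRun(base, "base", f1); writeRun(exp4, "exp", f2)
  sq <- sampleQrels(qrels, c(f1, f2), seed = seed + 1L)
  list(baseline = suppressWarnings(
         evaluateRun(base, qrels, sq))$means[["infNDCG"]],
       expanded = suppressWarnings(
         evaluateRun(exp4, qrels, sq))$means[["infNDCG"]])
}
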