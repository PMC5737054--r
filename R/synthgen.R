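#' Configuration for the synthetic test-collection generator
#'
#' The generator builds a complete offline collection — JSON corpus,
#' synonym table, query file and graded qrels — around a set of latent
#' concepts. Each concept has one query-side surface token plus
#' `synonyms_per_concept` document-side synonym forms, all registered in
#' the synonym table. With probability `mismatch_rate` a concept is
#' "masked": documents mention it only through synonym forms, never the
#' query-side token, so baseline retrieval misses it and expansion can
#' recover it — vocabulary mismatch as a tunable ground truth.
#'
#' Relevance grades come from exact concept coverage: a document covering
#' at least `theta2` of a query's concepts is fully relevant (grade 2), at
#' least `theta1` partially (grade 1). Query concepts are drawn from a
#' randomly chosen document's concepts, so every query has at least one
#' fully relevant document by construction.
#'
#' @param n_docs Documents in the corpus.
#' @param n_concepts Latent concepts.
#' @param synonyms_per_concept Document-side surface forms per concept.
#' @param doc_concepts Concepts mentioned per document.
#' @param query_concepts Concepts per query (<= `doc_concepts`).
#' @param n_queries Number of queries.
#' @param mismatch_rate Probability a concept is masked (rho in [0, 1]).
#' @param noise_tokens Zipf-distributed filler tokens per document.
#' @param theta1,theta2 Coverage thresholds for grades 1 and 2
#'   (0 < theta1 < theta2 <= 1).
#' @param strata_spec List of `c(depth, rate)` pairs with increasing
#'   depths, for [sampleQrels()].
#' @param seed Integer seed fixing every random draw.
#' @return A validated `SynthConfig` list.
#' @export
synthConfig <- function(n_docs = 500L, n_concepts = 30L,
                        synonyms_per_concept = 3L, doc_concepts = 3L,
                        query_concepts = 2L, n_queries = 10L,
                        mismatch_rate = 0.5, noise_tokens = 30L,
                        theta1 = 0.5, theta2 = 1.0,
                        strata_spec = list(c(15, 1.0), c(100, 0.3)),
                        seed = 1L) {
  cfg <- list(n_docs = as.integer(n_docs),
              n_concepts = as.integer(n_concepts),
              synonyms_per_concept = as.integer(synonyms_per_concept),
              doc_concepts = as.integer(doc_concepts),
              query_concepts = as.integer(query_concepts),
              n_queries = as.integer(n_queries),
              mismatch_rate = mismatch_rate,
              noise_tokens = as.integer(noise_tokens),
              theta1 = theta1, theta2 = theta2,
              strata_spec = strata_spec, seed = as.integer(seed))
  with(cfg, {
    if (doc_concepts > n_concepts)
      stop("infeasible config: doc_concepts > n_concepts")
    if (query_concepts > doc_concepts)
      stop("infeasible config: query_concepts > doc_concepts ",
           "(queries are drawn from a document's concepts)")
    if (mismatch_rate < 0 || mismatch_rate > 1)
      stop("mismatch_rate must lie in [0, 1]")
    if (!(theta1 > 0 && theta1 < theta2 && theta2 <= 1))
      stop("need 0 < theta1 < theta2 <= 1")
    if (n_docs < 1 || n_queries < 1 || synonyms_per_concept < 1)
      stop("n_docs, n_queries and synonyms_per_concept must be positive")
    for (s in strata_spec)
      if (length(s) != 2 || s[2] <= 0 || s[2] > 1)
        stop("strata_spec entries must be c(depth, rate) with rate in (0,1]")
  })
  class(cfg) <- "SynthConfig"
  cfg
}

zipfSample <- function(vocab, n, exponent = 1.1) {
  p <- seq_along(vocab)^(-exponent)
  sample(vocab, n, replace = TRUE, prob = p / sum(p))
}

#' Generate a complete synthetic test collection
#'
#' Writes four artifacts under `dir`, all in the formats the rest of the
#' toolkit consumes: a corpus (directory of JSON files, or a single
#' `corpus.jsonl`), `synonyms.tsv`, `queries.tsv` and `qrels.txt`
#' (relevant documents only). All randomness flows from `cfg$seed`;
#' identical configurations produce byte-identical outputs.
#'
#' @param cfg A [synthConfig()].
#' @param dir Output directory (created if needed).
#' @param corpus_format `"dir"` (one `.json` file per record) or
#'   `"jsonl"` (one object per line; faster for replicate studies).
#'   Every record carries an `id` field matching the qrels doc_ids; load
#'   `"jsonl"` corpora with `loadCorpus(path, id_field = "id")` (the
#'   `"dir"` filename stems already equal the ids).
#' @return List with the four paths (`corpus`, `synonyms`, `queries`,
#'   `qrels`) and `truth`: the generator's ground truth
#'   (`doc_concepts` list, `query_concepts` list, `masked` logical
#'   vector, `grades` data frame of every nonzero (qid, doc_id, grade)).
#' @export
generateCollection <- function(cfg, dir, corpus_format = c("dir", "jsonl")) {
  stopifnot(inherits(cfg, "SynthConfig"))
  corpus_format <- match.arg(corpus_format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)

  C <- cfg$n_concepts
  qtok <- sprintf("conc%03dq", seq_len(C))
  syn <- lapply(seq_len(C), function(i)
    sprintf("conc%03ds%d", i, seq_len(cfg$synonyms_per_concept)))
  masked <- stats::runif(C) < cfg$mismatch_rate
  noise_vocab <- sprintf("noise%03d", seq_len(200L))

  # documents
  doc_ids <- sprintf("d%04d", seq_len(cfg$n_docs))
  doc_concepts <- vector("list", cfg$n_docs)
  docs_json <- character(cfg$n_docs)
  for (d in seq_len(cfg$n_docs)) {
    cs <- sort(sample.int(C, cfg$doc_concepts))
    doc_concepts[[d]] <- cs
    surfaces <- vapply(cs, function(i) {
      if (masked[i]) syn[[i]][sample.int(length(syn[[i]]), 1L)] else qtok[i]
    }, character(1))
    noise <- zipfSample(noise_vocab, cfg$noise_tokens)
    rec <- list(
      id = doc_ids[d],
      title = paste(surfaces, collapse = " "),
      description = paste(noise[seq_len(ceiling(length(noise) / 2))],
                          collapse = " "),
      metadata = list(
        keywords = as.list(surfaces),
        source = list(repository = paste(
          noise[seq.int(ceiling(length(noise) / 2) + 1L, length(noise))],
          collapse = " "))))
    docs_json[d] <- as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
  }
  if (corpus_format == "dir") {
    corpus_path <- file.path(dir, "corpus")
    dir.create(corpus_path, showWarnings = FALSE)
    for (d in seq_len(cfg$n_docs))
      writeLines(docs_json[d], file.path(corpus_path,
                                         paste0(doc_ids[d], ".json")))
  } else {
    corpus_path <- file.path(dir, "corpus.jsonl")
    writeLines(docs_json, corpus_path)
  }

  # synonym table: query-side token -> all synonym surface forms
  syn_path <- file.path(dir, "synonyms.tsv")
  writeLines(vapply(seq_len(C), function(i)
    paste(c(qtok[i], syn[[i]]), collapse = "\t"), character(1)), syn_path)

  # queries: concepts of a randomly chosen document, phrased with the
  # lead-in and stopwords the preprocessor must strip
  qids <- sprintf("Q%02d", seq_len(cfg$n_queries))
  query_concepts <- vector("list", cfg$n_queries)
  qlines <- character(cfg$n_queries)
  for (q in seq_len(cfg$n_queries)) {
    seed_doc <- sample.int(cfg$n_docs, 1L)
    cs <- sort(sample(doc_concepts[[seed_doc]], cfg$query_concepts))
    query_concepts[[q]] <- cs
    qlines[q] <- paste0(qids[q], "\t",
                        paste("search for the",
                              paste(qtok[cs], collapse = " and ")))
  }
  q_path <- file.path(dir, "queries.tsv")
  writeLines(qlines, q_path)

  # grades from exact concept coverage
  rows <- list()
  for (q in seq_len(cfg$n_queries)) {
    cov <- vapply(doc_concepts, function(cs)
      length(intersect(cs, query_concepts[[q]])), integer(1)) /
      cfg$query_concepts
    grade <- ifelse(cov >= cfg$theta2, 2L, ifelse(cov >= cfg$theta1, 1L, 0L))
    keep <- which(grade > 0L)
    if (length(keep))
      rows[[q]] <- data.frame(qid = qids[q], doc_id = doc_ids[keep],
                              grade = grade[keep], stringsAsFactors = FALSE)
  }
  grades <- do.call(rbind, rows)
  class(grades) <- c("Qrels", "data.frame")
  qrels_path <- file.path(dir, "qrels.txt")
  writeQrels(grades, qrels_path)

  list(corpus = corpus_path, synonyms = syn_path, queries = q_path,
       qrels = qrels_path,
       truth = list(doc_concepts = stats::setNames(doc_concepts, doc_ids),
                    query_concepts = stats::setNames(query_concepts, qids),
                    masked = masked, grades = grades,
                    query_tokens = qtok))
}

#' Stratified sampling of a judging pool from submitted runs
#'
#' Emulates the challenge's judging economy: the pool is the union of the
#' top-`depth` documents across the supplied runs; documents whose best
#' rank falls within the first depth go to stratum 1 (typically sampled
#' exhaustively), deeper documents to later strata. Each (query, stratum)
#' is sampled without replacement at its rate using a
#' floor-plus-randomized-remainder rule, so sample sizes are deterministic
#' given the seed. Grades are copied from the qrels for sampled documents
#' only (absent pairs are judged not relevant, grade 0).
#'
#' @param qrels A `Qrels` holding the ground-truth grades.
#' @param run_files Non-empty character vector of TREC run file paths.
#' @param strata_spec List of `c(depth, rate)` with increasing depths.
#' @param seed Integer seed for the sampling draws.
#' @return A [sampledQrels()] object.
#' @export
sampleQrels <- function(qrels, run_files,
                        strata_spec = list(c(15, 1.0), c(100, 0.3)),
                        seed = 1L) {
  if (!length(run_files)) stop("need at least one run file to pool")
  depths <- vapply(strata_spec, `[[`, numeric(1), 1L)
  if (is.unsorted(depths, strictly = TRUE))
    stop("strata_spec depths must be strictly increasing")
  runs <- lapply(run_files, readRun)
  all_runs <- do.call(rbind, runs)
  max_depth <- max(depths)
  pooled <- all_runs[all_runs$rank <= max_depth, , drop = FALSE]
  if (!nrow(pooled)) stop("no documents within pooling depth")

  # best (minimum) rank of each (qid, doc_id) across runs
  key <- paste(pooled$qid, pooled$doc_id, sep = "\r")
  best_rank <- tapply(pooled$rank, key, min)
  parts <- strsplit(names(best_rank), "\r", fixed = TRUE)
  pool <- data.frame(
    qid = vapply(parts, `[[`, character(1), 1L),
    doc_id = vapply(parts, `[[`, character(1), 2L),
    stratum = as.character(findInterval(as.numeric(best_rank) - 1, depths) + 1L),
    stringsAsFactors = FALSE)
  pool <- pool[order(pool$qid, as.integer(pool$stratum), pool$doc_id), ]
  rownames(pool) <- NULL

  set.seed(seed)
  gkey <- paste(qrels$qid, qrels$doc_id)
  gmap <- qrels$grade
  names(gmap) <- gkey

  rates_rows <- list(); grade_rows <- list()
  for (qid in unique(pool$qid)) {
    for (s in seq_along(strata_spec)) {
      docs <- pool$doc_id[pool$qid == qid & pool$stratum == as.character(s)]
      rate <- strata_spec[[s]][2]
      rates_rows[[length(rates_rows) + 1L]] <-
        data.frame(qid = qid, stratum = as.character(s), rate = rate,
                   stringsAsFactors = FALSE)
      if (!length(docs)) next
      target <- length(docs) * rate
      n_take <- floor(target) +
        (stats::runif(1) < (target - floor(target)))
      if (n_take == 0L) next
      take <- sort(sample(docs, n_take))
      g <- gmap[paste(qid, take)]
      g[is.na(g)] <- 0L
      grade_rows[[length(grade_rows) + 1L]] <-
        data.frame(qid = qid, doc_id = take, grade = as.integer(g),
                   stringsAsFactors = FALSE)
    }
  }
  grades <- if (length(grade_rows)) do.call(rbind, grade_rows)
  else data.frame(qid = character(0), doc_id = character(0),
                  grade = integer(0), stringsAsFactors = FALSE)
  rownames(grades) <- NULL
  sampledQrels(pool, do.call(rbind, rates_rows), grades)
}
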