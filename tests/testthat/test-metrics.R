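mkRL <- function(qid, docs) {
  rl <- data.frame(qid = rep(qid, length(docs)), doc_id = docs,
                   rank = seq_along(docs),
                   score = rev(seq_along(docs)) + 0.5,
                   stringsAsFactors = FALSE)
  class(rl) <- c("RankedList", "data.frame")
  rl
}
mkQrels <- function(qid, docs, grades) {
  q <- data.frame(qid = rep(qid, length(docs)), doc_id = docs,
                  grade = as.integer(grades), stringsAsFactors = FALSE)
  class(q) <- c("Qrels", "data.frame")
  q
}

test_that("precision at k counts graded hits with padding", {
  docs <- sprintf("d%02d", 1:10)
  qr <- mkQrels("Q1", docs, c(2, 1, 0, 2, 0, 0, 1, 0, 0, 0))
  rl <- mkRL("Q1", docs)
  expect_equal(precisionAtK(rl, qr, 10, min_grade = 1), 0.4)
  expect_equal(precisionAtK(rl, qr, 10, min_grade = 2), 0.2)
  # short lists pad with non-relevant
  rl3 <- mkRL("Q1", c("a", "b", "c"))
  qr3 <- mkQrels("Q1", c("a", "b", "c"), c(2, 2, 2))
  expect_equal(precisionAtK(rl3, qr3, 10, min_grade = 2), 0.3)
})

test_that("NDCG matches the hand-evaluated worked example", {
  # ranked grades [1,2,0]; full grade multiset {2,1}
  # DCG = 1 + 2/log2(3) = 2.26186; iDCG = 2 + 1/log2(3) = 2.63093
  rl <- mkRL("Q1", c("x", "y", "z"))
  qr <- mkQrels("Q1", c("x", "y"), c(1, 2))
  hand_dcg <- 1 + 2 / log2(3)
  hand_idcg <- 2 + 1 / log2(3)
  expect_equal(ndcgAtK(rl, qr, 10), hand_dcg / hand_idcg, tolerance = 1e-12)
  expect_equal(ndcgAtK(rl, qr, 10), 0.85972, tolerance = 1e-4)

  # ideal ordering scores exactly 1
  rl_ideal <- mkRL("Q1", c("y", "x", "z"))
  expect_equal(ndcgAtK(rl_ideal, qr, 10), 1)
  # no relevant docs: 0/0 defined as 0
  expect_equal(ndcgAtK(rl, mkQrels("Q1", "x", 0), 10), 0)
})

test_that("average precision matches hand evaluation and edge rules", {
  rl <- mkRL("Q1", c("a", "b", "c", "d"))
  qr <- mkQrels("Q1", c("a", "c"), c(1, 2))
  expect_equal(averagePrecision(rl, qr), (1 + 2 / 3) / 2, tolerance = 1e-12)
  # all R relevant on top
  qr2 <- mkQrels("Q1", c("a", "b"), c(2, 1))
  expect_equal(averagePrecision(rl, qr2), 1)
  expect_equal(averagePrecision(rl, mkQrels("Q1", "a", 0)), 0)  # R = 0
})

test_that("exact metrics agree with naive oracles on random instances", {
  set.seed(101)
  doc_pool <- sprintf("d%03d", 1:60)
  for (i in 1:200) {
    qid <- paste0("Q", i)
    rl <- randomRankedList(qid, doc_pool, sample(1:30, 1))
    qr <- randomQrels(qid, doc_pool)
    expect_equal(precisionAtK(rl, qr, 10, 1),
                 oraclePrecisionAtK(rl, qr, 10, 1), tolerance = 1e-9)
    expect_equal(precisionAtK(rl, qr, 10, 2),
                 oraclePrecisionAtK(rl, qr, 10, 2), tolerance = 1e-9)
    expect_equal(ndcgAtK(rl, qr, 10), oracleNdcgAtK(rl, qr, 10),
                 tolerance = 1e-9)
    expect_equal(averagePrecision(rl, qr), oracleAveragePrecision(rl, qr),
                 tolerance = 1e-9)
  }
})

test_that("metrics stay in [0,1] and ignore the non-relevant tail order", {
  set.seed(77)
  doc_pool <- sprintf("d%03d", 1:40)
  qid <- "Q1"
  qr <- mkQrels(qid, c("d001", "d002", "d003"), c(2, 1, 1))
  rl <- mkRL(qid, c("d001", "d002", "d003", "d010", "d011", "d012"))
  # permute the equally-scored non-relevant tail
  rl2 <- mkRL(qid, c("d001", "d002", "d003", "d012", "d010", "d011"))
  sq <- sampledQrels(
    data.frame(qid = qid, doc_id = qr$doc_id, stratum = "1"),
    data.frame(qid = qid, stratum = "1", rate = 1),
    data.frame(qid = qid, doc_id = qr$doc_id, grade = qr$grade))
  for (f in list(
    function(r) precisionAtK(r, qr, 10, 1),
    function(r) precisionAtK(r, qr, 10, 2),
    function(r) ndcgAtK(r, qr, 10),
    function(r) averagePrecision(r, qr),
    function(r) infAP(r, sq),
    function(r) infNDCG(r, sq))) {
    v <- f(rl)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(f(rl2), v, tolerance = 1e-12)
  }
})

census_sq <- function(qr) {
  sampledQrels(
    data.frame(qid = qr$qid, doc_id = qr$doc_id, stratum = "1",
               stringsAsFactors = FALSE),
    data.frame(qid = unique(qr$qid), stratum = "1", rate = 1,
               stringsAsFactors = FALSE),
    data.frame(qid = qr$qid, doc_id = qr$doc_id, grade = qr$grade,
               stringsAsFactors = FALSE))
}

test_that("fully sampled pools reduce the inferred metrics exactly", {
  set.seed(202)
  doc_pool <- sprintf("d%03d", 1:30)
  for (i in 1:100) {
    qid <- paste0("Q", i)
    # ranked list covers the whole pool so the ideal fills coincide
    rl <- randomRankedList(qid, doc_pool, 30)
    qr <- randomQrels(qid, doc_pool)
    sq <- census_sq(qr)
    expect_equal(infAP(rl, sq), averagePrecision(rl, qr), tolerance = 1e-9)
    expect_equal(infNDCG(rl, sq), ndcgAtK(rl, qr, k = 30), tolerance = 1e-9)
  }
})

test_that("infAP matches the smoothed estimator transcript on samples", {
  # fixed 8-doc pool, single stratum at rate 1/2
  pool_docs <- letters[1:8]
  true_grades <- c(a = 2L, b = 0L, c = 1L, d = 0L,
                   e = 2L, f = 0L, g = 1L, h = 0L)
  rl <- mkRL("Q1", c("a", "b", "c", "x1", "d", "e", "f", "g", "x2", "h"))
  vals_pkg <- c(); vals_orc <- c()
  combos <- utils::combn(8, 4)
  for (j in seq_len(ncol(combos))) {
    samp <- pool_docs[combos[, j]]
    sq <- sampledQrels(
      data.frame(qid = "Q1", doc_id = pool_docs, stratum = "1",
                 stringsAsFactors = FALSE),
      data.frame(qid = "Q1", stratum = "1", rate = 0.5,
                 stringsAsFactors = FALSE),
      data.frame(qid = "Q1", doc_id = samp,
                 grade = unname(true_grades[samp]),
                 stringsAsFactors = FALSE))
    vals_pkg <- c(vals_pkg, infAP(rl, sq))
    vals_orc <- c(vals_orc, oracleInfAP(rl, pool_docs, true_grades[samp],
                                        rate = 0.5))
  }
  # per-sample agreement and agreement of the enumerated expectation
  expect_equal(vals_pkg, vals_orc, tolerance = 1e-9)
  expect_equal(mean(vals_pkg), mean(vals_orc), tolerance = 1e-9)
  # no sampled relevant docs -> 0
  sq0 <- sampledQrels(
    data.frame(qid = "Q1", doc_id = pool_docs, stratum = "1",
               stringsAsFactors = FALSE),
    data.frame(qid = "Q1", stratum = "1", rate = 0.5,
               stringsAsFactors = FALSE),
    data.frame(qid = "Q1", doc_id = c("b", "d"), grade = c(0L, 0L),
               stringsAsFactors = FALSE))
  expect_equal(infAP(rl, sq0), 0)
})

test_that("infNDCG matches a step-by-step two-stratum hand evaluation", {
  # pool: stratum 1 (rate 1.0) = {a,b,c} all judged (2,1,0);
  #       stratum 2 (rate 0.5) = {d,e,f}, sampled {d=1, f=0}
  sq <- sampledQrels(
    data.frame(qid = "Q1", doc_id = c("a", "b", "c", "d", "e", "f"),
               stratum = c("1", "1", "1", "2", "2", "2"),
               stringsAsFactors = FALSE),
    data.frame(qid = "Q1", stratum = c("1", "2"), rate = c(1.0, 0.5),
               stringsAsFactors = FALSE),
    data.frame(qid = "Q1", doc_id = c("a", "b", "c", "d", "f"),
               grade = c(2L, 1L, 0L, 1L, 0L), stringsAsFactors = FALSE))
  rl <- mkRL("Q1", c("a", "d", "e", "b", "g", "c"))
  # estimated DCG: 2/log2(2) + 1/log2(3) + gbar2/log2(4) + 1/log2(5)
  # with gbar2 = mean(1, 0) = 0.5; ranks 5 (unpooled) and 6 (grade 0) add 0
  hand_dcg <- 2 + 1 / log2(3) + 0.5 / log2(4) + 1 / log2(5)
  # estimated counts: N2 = 1/1.0 = 1; N1 = 1/1.0 + 1/0.5 = 3
  hand_idcg <- 2 + (1 / log2(3) + 1 / log2(4) + 1 / log2(5))
  expect_equal(infNDCG(rl, sq), hand_dcg / hand_idcg, tolerance = 1e-12)
  # empty ranked list -> 0
  expect_equal(infNDCG(mkRL("Q1", character(0)), sq), 0)
})

test_that("fractional estimated counts fill the ideal at the next rank", {
  # one stratum at rate 0.4: sampled one grade-2 doc -> N2 = 2.5
  sq <- sampledQrels(
    data.frame(qid = "Q1", doc_id = letters[1:5], stratum = "1",
               stringsAsFactors = FALSE),
    data.frame(qid = "Q1", stratum = "1", rate = 0.4,
               stringsAsFactors = FALSE),
    data.frame(qid = "Q1", doc_id = c("a", "b"), grade = c(2L, 0L),
               stringsAsFactors = FALSE))
  rl <- mkRL("Q1", c("a", "b", "c", "d", "e"))
  gbar <- mean(c(2, 0))
  hand_dcg <- 2 + 0 + gbar * (1 / log2(4) + 1 / log2(5) + 1 / log2(6))
  hand_idcg <- 2 * (1 + 1 / log2(3)) + 0.5 * 2 / log2(4)
  expect_equal(infNDCG(rl, sq), hand_dcg / hand_idcg, tolerance = 1e-12)
})

test_that("infNDCG error approaches zero as sampling rates rise", {
  set.seed(303)
  doc_pool <- sprintf("d%03d", 1:40)
  qid <- "Q1"
  qr <- randomQrels(qid, doc_pool)
  rl <- randomRankedList(qid, doc_pool, 40)
  exact <- ndcgAtK(rl, qr, k = 40)
  judged <- qr$doc_id
  mean_err <- vapply(c(0.25, 0.5, 0.75, 1.0), function(p) {
    errs <- vapply(1:200, function(r) {
      n_take <- max(1L, round(p * length(judged)))
      samp <- sample(judged, n_take)
      sq <- sampledQrels(
        data.frame(qid = qid, doc_id = judged, stratum = "1",
                   stringsAsFactors = FALSE),
        data.frame(qid = qid, stratum = "1", rate = p,
                   stringsAsFactors = FALSE),
        data.frame(qid = qid, doc_id = samp,
                   grade = qr$grade[match(samp, qr$doc_id)],
                   stringsAsFactors = FALSE))
      abs(infNDCG(rl, sq) - exact)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mean_err) <= 1e-9))
  expect_equal(mean_err[4], 0, tolerance = 1e-9)
})

test_that("a pooled stratum without a rate is an error", {
  expect_error(sampledQrels(
    data.frame(qid = "Q1", doc_id = "a", stratum = "2",
               stringsAsFactors = FALSE),
    data.frame(qid = "Q1", stratum = "1", rate = 1,
               stringsAsFactors = FALSE),
    data.frame(qid = character(0), doc_id = character(0),
               grade = integer(0))), "without a sampling rate")
  expect_error(sampledQrels(
    data.frame(qid = "Q1", doc_id = "a", stratum = "1",
               stringsAsFactors = FALSE),
    data.frame(qid = "Q1", stratum = "1", rate = 1,
               stringsAsFactors = FALSE),
    data.frame(qid = "Q1", doc_id = "zz", grade = 1L,
               stringsAsFactors = FALSE)), "not present in the pool")
})
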