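#' Read graded relevance judgments (qrels)
#'
#' Standard 4-column whitespace-separated format `qid 0 doc_id grade`,
#' grades in {0, 1, 2} (not / partially / fully relevant). A (qid, doc_id)
#' pair absent from the file is unjudged.
#'
#' @param path Qrels file.
#' @return A `Qrels`: data frame with columns `qid`, `doc_id`, `grade`.
#' @export
readQrels <- function(path) {
  if (!file.exists(path)) stop("qrels file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  parts <- strsplit(lines[keep], "[[:space:]]+")
  bad <- which(vapply(parts, length, integer(1)) != 4L)
  if (length(bad))
    stop("qrels line ", which(keep)[bad[1]], ": expected 4 columns")
  m <- do.call(rbind, parts)
  grade <- suppressWarnings(as.integer(m[, 4]))
  if (anyNA(grade) || any(!grade %in% 0:2))
    stop("qrels grades must be integers in {0,1,2}")
  q <- data.frame(qid = m[, 1], doc_id = m[, 3], grade = grade,
                  stringsAsFactors = FALSE)
  if (anyDuplicated(paste(q$qid, q$doc_id)))
    stop("duplicate (qid, doc_id) pair in qrels")
  class(q) <- c("Qrels", "data.frame")
  q
}

#' Write qrels in the standard 4-column format
#'
#' @param qrels A `Qrels` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeQrels <- function(qrels, path) {
  writeLines(sprintf("%s 0 %s %d", qrels$qid, qrels$doc_id, qrels$grade),
             path)
  invisible(path)
}

#' Construct stratified-sampled qrels
#'
#' @param pool Data frame `qid`, `doc_id`, `stratum` — every pooled doc.
#' @param rates Data frame `qid`, `stratum`, `rate` with rates in (0, 1].
#' @param grades Data frame `qid`, `doc_id`, `grade` for sampled docs only.
#' @return A `SampledQrels` list with the three components, validated:
#'   every graded doc is pooled, every pooled doc's stratum has a rate.
#' @export
sampledQrels <- function(pool, rates, grades) {
  stopifnot(all(c("qid", "doc_id", "stratum") %in% names(pool)),
            all(c("qid", "stratum", "rate") %in% names(rates)),
            all(c("qid", "doc_id", "grade") %in% names(grades)))
  if (any(rates$rate <= 0) || any(rates$rate > 1))
    stop("sampling rates must lie in (0, 1]")
  pk <- paste(pool$qid, pool$doc_id)
  if (anyDuplicated(pk)) stop("duplicate pooled (qid, doc_id)")
  if (!all(paste(grades$qid, grades$doc_id) %in% pk))
    stop("graded doc not present in the pool")
  need <- unique(paste(pool$qid, pool$stratum))
  have <- paste(rates$qid, rates$stratum)
  if (!all(need %in% have))
    stop("pooled stratum without a sampling rate: ",
         setdiff(need, have)[1])
  structure(list(pool = pool, rates = rates, grades = grades),
            class = "SampledQrels")
}

#' Read stratified-sampled qrels
#'
#' Dialect: header lines `#rate <qid> <stratum_id> <p>` declare per-query
#' per-stratum sampling rates; body lines are `qid stratum_id doc_id
#' grade` for every pooled document, with grade `-` for pooled-but-
#' unsampled documents and an integer in {0,1,2} for sampled ones.
#'
#' @param path Sampled-qrels file.
#' @return A [sampledQrels()] object.
#' @export
readSampledQrels <- function(path) {
  if (!file.exists(path)) stop("sampled qrels file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  rates <- list(); pool <- list(); grades <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    parts <- strsplit(ln, "[[:space:]]+")[[1]]
    if (startsWith(ln, "#")) {
      if (parts[1] != "#rate") next  # plain comment
      if (length(parts) != 4L)
        stop("line ", i, ": #rate expects 'qid stratum rate'")
      p <- suppressWarnings(as.numeric(parts[4]))
      if (is.na(p)) stop("line ", i, ": unreadable rate")
      rates[[length(rates) + 1L]] <-
        data.frame(qid = parts[2], stratum = parts[3], rate = p,
                   stringsAsFactors = FALSE)
      next
    }
    if (length(parts) != 4L)
      stop("line ", i, ": expected 'qid stratum doc_id grade'")
    pool[[length(pool) + 1L]] <-
      data.frame(qid = parts[1], doc_id = parts[3], stratum = parts[2],
                 stringsAsFactors = FALSE)
    if (parts[4] != "-") {
      g <- suppressWarnings(as.integer(parts[4]))
      if (is.na(g) || !g %in% 0:2)
        stop("line ", i, ": grade must be -, 0, 1 or 2")
      grades[[length(grades) + 1L]] <-
        data.frame(qid = parts[1], doc_id = parts[3], grade = g,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(pool)) stop("sampled qrels file has no pooled documents")
  sampledQrels(do.call(rbind, pool),
               do.call(rbind, rates),
               if (length(grades)) do.call(rbind, grades)
               else data.frame(qid = character(0), doc_id = character(0),
                               grade = integer(0), stringsAsFactors = FALSE))
}

#' Write stratified-sampled qrels
#'
#' @param sq A `SampledQrels`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeSampledQrels <- function(sq, path) {
  stopifnot(inherits(sq, "SampledQrels"))
  hdr <- sprintf("#rate %s %s %s", sq$rates$qid, sq$rates$stratum,
                 formatC(sq$rates$rate, format = "fg", digits = 10))
  gk <- paste(sq$grades$qid, sq$grades$doc_id)
  gmap <- sq$grades$grade
  names(gmap) <- gk
  pk <- paste(sq$pool$qid, sq$pool$doc_id)
  gcol <- ifelse(pk %in% gk, as.character(gmap[pk]), "-")
  body <- sprintf("%s %s %s %s", sq$pool$qid, sq$pool$stratum,
                  sq$pool$doc_id, gcol)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @export
print.SampledQrels <- function(x, ...) {
  cat("<SampledQrels> ", length(unique(x$pool$qid)), " queries, ",
      nrow(x$pool), " pooled docs, ", nrow(x$grades), " sampled\n", sep = "")
  invisible(x)
}
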