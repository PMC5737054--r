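#' Write ranked lists as a TREC run file
#'
#' One line per retrieved document, space-separated:
#' `qid Q0 doc_id rank score run_id`, queries in input order, scores
#' printed with fixed 6-decimal formatting (treceval-compatible, stable
#' diffs). Queries with empty result lists contribute zero lines.
#'
#' @param lists A `RankedList` or list of them (one per query).
#' @param run_id Whitespace-free run identifier.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeRun <- function(lists, run_id, path) {
  if (grepl("[[:space:]]", run_id)) stop("run_id must be whitespace-free")
  if (inherits(lists, "RankedList")) lists <- list(lists)
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot write run file: ", path))
  on.exit(close(con))
  for (rl in lists) {
    if (!nrow(rl)) next
    lines <- sprintf("%s Q0 %s %d %.6f %s",
                     rl$qid, rl$doc_id, rl$rank, rl$score, run_id)
    writeLines(lines, con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read a TREC run file
#'
#' @param path Run file with lines `qid Q0 doc_id rank score run_id`.
#' @return Data frame with columns `qid`, `doc_id`, `rank`, `score`,
#'   `run_id`, in file order.
#' @export
readRun <- function(path) {
  if (!file.exists(path)) stop("run file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(qid = character(0), doc_id = character(0),
                      rank = integer(0), score = numeric(0),
                      run_id = character(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- vapply(parts, length, integer(1)) != 6L
  if (any(bad)) stop("malformed run line(s): ",
                     paste(utils::head(which(bad), 5), collapse = ", "))
  m <- do.call(rbind, parts)
  data.frame(qid = m[, 1], doc_id = m[, 3],
             rank = as.integer(m[, 4]), score = as.numeric(m[, 5]),
             run_id = m[, 6], stringsAsFactors = FALSE)
}

# Split a run data frame into per-query RankedLists preserving file order.
runToRankedLists <- function(run) {
  qids <- unique(run$qid)
  lapply(qids, function(q) {
    rl <- run[run$qid == q, c("qid", "doc_id", "rank", "score")]
    rownames(rl) <- NULL
    class(rl) <- c("RankedList", "data.frame")
    rl
  })
}
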