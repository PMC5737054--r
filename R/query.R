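#' Expansion configuration: term cap and clause weights
#'
#' Bundles the per-token MeSH term cap with the relative clause weights.
#' The ratio string follows the "MeSH:Baseline" orientation: `"1:5"` means
#' the expansion clause contributes at one-fifth the weight of the
#' baseline clause. Weights may also be given directly, which permits the
#' opposite orientation if a caller wants it.
#'
#' @param max_terms Non-negative integer per-token cap (0 = no expansion).
#' @param ratio Ratio string `"a:b"` (mesh:baseline); ignored when both
#'   weights are supplied.
#' @param mesh_weight,baseline_weight Positive clause weights.
#' @return An `ExpansionConfig` list: `max_terms`, `mesh_weight`,
#'   `baseline_weight`.
#' @examples
#' expansionConfig(5, "1:5")
#' @export
expansionConfig <- function(max_terms, ratio = NULL,
                            mesh_weight = NULL, baseline_weight = NULL) {
  stopifnot(is.numeric(max_terms), length(max_terms) == 1L, max_terms >= 0)
  if (is.null(mesh_weight) || is.null(baseline_weight)) {
    if (is.null(ratio)) ratio <- "1:1"
    w <- parseRatio(ratio)
    mesh_weight <- w[["mesh"]]
    baseline_weight <- w[["baseline"]]
  }
  stopifnot(baseline_weight > 0, max_terms == 0 || mesh_weight > 0)
  structure(list(max_terms = as.integer(max_terms),
                 mesh_weight = mesh_weight,
                 baseline_weight = baseline_weight),
            class = "ExpansionConfig")
}

#' Parse a "mesh:baseline" weight ratio string
#'
#' @param ratio String like `"1:5"`; either side may be a decimal.
#' @return Named numeric vector with elements `mesh` and `baseline`.
#' @export
parseRatio <- function(ratio) {
  parts <- strsplit(ratio, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("ratio must look like 'a:b', got: ", ratio)
  v <- suppressWarnings(as.numeric(parts))
  if (anyNA(v) || any(v < 0)) stop("invalid ratio: ", ratio)
  c(mesh = v[1], baseline = v[2])
}

#' Load the packaged English stopword list
#'
#' @param path Optional override; defaults to the packaged fixture.
#' @return Character vector of lowercase stopwords.
#' @export
loadStopwords <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "stopwords_en.txt", package = "meshquery")
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Load the packaged common-phrase removal patterns
#'
#' One pattern per line; each is removed from the lowercased query as a
#' whole-word regular expression before tokenization. The list is
#' configuration, not hard-coded truth: edit or replace it freely.
#'
#' @param path Optional override; defaults to the packaged fixture.
#' @return Character vector of phrase patterns.
#' @export
loadPhrasePatterns <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "phrase_patterns.txt", package = "meshquery")
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Preprocess a raw query into the baseline token list
#'
#' Lowercases the query, removes common lead-in words and phrases such as
#' "search for" with whole-word regular expressions, tokenizes with the
#' index tokenizer, and drops English stopwords. The result is the
#' "baseline query" that expansion builds upon.
#'
#' @param raw_query Raw query string.
#' @param stop_list Character vector of stopwords (lowercase).
#' @param phrase_patterns Character vector of phrases to remove.
#' @return Character vector of baseline tokens; empty (with a warning)
#'   when everything is removed.
#' @examples
#' preprocessQuery("Search for datasets of liver cancer",
#'                 stop_list = c("of"), phrase_patterns = c("search for"))
#' @export
preprocessQuery <- function(raw_query,
                            stop_list = loadStopwords(),
                            phrase_patterns = loadPhrasePatterns()) {
  q <- stringi::stri_trans_tolower(raw_query)
  # longest patterns first so "datasets of" wins over "datasets"
  for (p in phrase_patterns[order(-nchar(phrase_patterns))]) {
    rx <- paste0("\\b\\Q", stringi::stri_trans_tolower(p), "\\E\\b")
    q <- stringi::stri_replace_all_regex(q, rx, " ")
  }
  toks <- tokenize(q)
  toks <- toks[!(toks %in% stop_list)]
  if (!length(toks))
    warning("query reduced to zero tokens after preprocessing: ",
            substr(raw_query, 1, 60))
  toks
}

#' Build a structured (baseline + expansion) query
#'
#' @param qid Query identifier.
#' @param raw_query Raw query text.
#' @param table A `SynonymTable` (may be empty).
#' @param config An [expansionConfig()].
#' @param stop_list,phrase_patterns Preprocessing fixtures.
#' @return A `StructuredQuery`: `qid`, `baseline_tokens`,
#'   `expansion_tokens`, `config`.
#' @export
structuredQuery <- function(qid, raw_query, table, config,
                            stop_list = loadStopwords(),
                            phrase_patterns = loadPhrasePatterns()) {
  baseline <- preprocessQuery(raw_query, stop_list, phrase_patterns)
  expansion <- if (config$max_terms > 0L)
    buildExpansionBag(baseline, table, config$max_terms)
  else character(0)
  structure(list(qid = as.character(qid),
                 baseline_tokens = baseline,
                 expansion_tokens = expansion,
                 config = config),
            class = "StructuredQuery")
}

#' @export
print.StructuredQuery <- function(x, ...) {
  cat("<StructuredQuery> ", x$qid, ": baseline [",
      paste(x$baseline_tokens, collapse = " "), "] + ",
      length(x$expansion_tokens), " expansion tokens, weights ",
      x$config$mesh_weight, ":", x$config$baseline_weight,
      " (mesh:baseline)\n", sep = "")
  invisible(x)
}

#' Read a query file
#'
#' UTF-8 text, one query per line, `qid<TAB>query text`.
#'
#' @param path Query file.
#' @return Data frame with columns `qid`, `text`.
#' @export
readQueries <- function(path) {
  if (!file.exists(path)) stop("query file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 2L
  if (any(bad)) stop("query file line(s) without a tab: ",
                     paste(which(bad), collapse = ", "))
  data.frame(qid = vapply(parts, `[[`, character(1), 1L),
             text = vapply(parts, function(p)
               paste(p[-1L], collapse = "\t"), character(1)),
             stringsAsFactors = FALSE)
}
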