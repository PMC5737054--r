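#' Load a MeSH synonym table from TSV
#'
#' The table maps lowercase query tokens to ordered lists of MeSH term
#' strings and stands in for a live Entrez lookup: the file's line and
#' column order is the canonical term order, which makes expansion
#' reproducible. Lines are `token<TAB>term1<TAB>term2...`; lines starting
#' with `#` are comments; a line without a tab is skipped with a warning.
#' A token appearing on several lines merges its lists, appending terms
#' not already present.
#'
#' @param path TSV file (UTF-8).
#' @return A `SynonymTable`: named list token -> character vector of terms.
#' @export
loadSynonyms <- function(path) {
  if (!file.exists(path)) stop("synonym table not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  entries <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln)) || startsWith(ln, "#")) next
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) {
      warning("synonym table line ", i, " has no tab-separated terms; skipped")
      next
    }
    token <- stringi::stri_trans_tolower(trimws(parts[1]))
    terms <- trimws(parts[-1])
    terms <- terms[nzchar(terms)]
    if (!nzchar(token) || !length(terms)) next
    prev <- entries[[token]]
    entries[[token]] <- c(prev, setdiff(terms, prev))
  }
  structure(entries, class = "SynonymTable")
}

#' @export
print.SynonymTable <- function(x, ...) {
  cat("<SynonymTable> ", length(x), " tokens, ",
      sum(lengths(unclass(x))), " terms\n", sep = "")
  invisible(x)
}

#' Look up MeSH terms for one token, capped at max_terms
#'
#' Returns the first `min(max_terms, available)` terms in table order; not
#' every token reaches the cap, and unknown tokens return none.
#'
#' @param table A `SynonymTable`.
#' @param token Query token (matched lowercase).
#' @param max_terms Non-negative cap on returned terms; 0 disables lookup.
#' @return Character vector of at most `max_terms` terms.
#' @export
meshLookup <- function(table, token, max_terms) {
  stopifnot(is.numeric(max_terms), max_terms >= 0)
  if (max_terms == 0) return(character(0))
  terms <- table[[stringi::stri_trans_tolower(token)]]
  if (is.null(terms)) return(character(0))
  utils::head(terms, max_terms)
}

#' Build the expansion token bag for a baseline query
#'
#' For each baseline token in order, up to `max_terms` MeSH terms are
#' fetched; all returned terms are combined as a single string, tokenized
#' with the index tokenizer (so multiword terms decompose into word
#' tokens), and deduplicated preserving first occurrence. The bag feeds
#' the optional ("should") expansion clause of the combined query.
#'
#' @param baseline_tokens Character vector of preprocessed query tokens.
#' @param table A `SynonymTable`.
#' @param max_terms Per-token cap; 0 yields an empty bag.
#' @return Character vector of expansion tokens (possibly empty).
#' @export
buildExpansionBag <- function(baseline_tokens, table, max_terms) {
  terms <- unlist(lapply(baseline_tokens, meshLookup,
                         table = table, max_terms = max_terms),
                  use.names = FALSE)
  if (!length(terms)) return(character(0))
  unique(tokenize(paste(terms, collapse = " ")))
}
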