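#' Tokenize text with Unicode word segmentation
#'
#' Splits text into word tokens at Unicode (UAX-29) word boundaries,
#' lowercases them, and drops segments that contain no word characters
#' (pure punctuation, whitespace). This is the single tokenizer used for
#' indexing, query processing and expansion-term decomposition, so that
#' query and document vocabularies agree.
#'
#' No stemming and no stop-wording is applied here: stopword removal is a
#' query-side preprocessing step (see [preprocessQuery()]), never an
#' index-side one.
#'
#' @param text Character vector; each element is tokenized independently.
#' @return For a single string, a character vector of tokens (possibly
#'   empty); for a character vector of length > 1, a list of such vectors.
#' @examples
#' tokenize("Gene Expression Omnibus")
#' tokenize("IL-6 pathway")
#' @export
tokenize <- function(text) {
  if (length(text) == 0L) return(character(0))
  text[is.na(text)] <- ""
  parts <- stringi::stri_split_boundaries(text, type = "word",
                                          skip_word_none = TRUE)
  parts <- lapply(parts, function(p) {
    p <- p[!is.na(p) & nzchar(p)]
    stringi::stri_trans_tolower(p)
  })
  if (length(text) == 1L) parts[[1L]] else parts
}
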