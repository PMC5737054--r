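#' Flatten a nested metadata record to path -> text fields
#'
#' Dataset metadata arrives as arbitrarily nested JSON. Records are stored
#' as independent flat documents: leaf scalars are joined under
#' dot-separated paths, list elements are merged under the parent path
#' (indices dropped) with values concatenated by single spaces, and a
#' catch-all field concatenates every field value in sorted-path order.
#' Relationships between sibling fields inside arrays of objects are
#' deliberately lost; all fields are treated as unstructured text.
#'
#' @param raw A parsed JSON tree (nested list of scalars/lists), e.g. from
#'   `jsonlite::fromJSON(..., simplifyVector = FALSE)`.
#' @param doc_id Non-empty document identifier.
#' @return A `MetadataRecord`: list with `doc_id`, `fields` (named
#'   character vector, flattened-path -> text) and `catchall` (single
#'   string). An empty tree yields empty `fields` and `catchall`.
#' @examples
#' flattenRecord(list(a = list(b = "x", c = list("y", "z"))), "d1")$fields
#' @export
flattenRecord <- function(raw, doc_id) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  acc <- new.env(parent = emptyenv())

  add <- function(path, value) {
    if (is.null(value) || length(value) == 0L) return(invisible())
    txt <- paste(scalarText(value), collapse = " ")
    if (!nzchar(txt)) return(invisible())
    prev <- if (exists(path, envir = acc, inherits = FALSE))
      get(path, envir = acc) else NULL
    assign(path, c(prev, txt), envir = acc)
  }

  walk <- function(node, path) {
    if (is.null(node)) return(invisible())
    if (is.list(node)) {
      nm <- names(node)
      if (is.null(nm) || all(!nzchar(nm))) {
        # array: indices dropped, children merged under the parent path
        for (el in node) walk(el, path)
      } else {
        for (i in seq_along(node)) {
          key <- nm[i]
          child <- if (nzchar(path)) paste(path, key, sep = ".") else key
          walk(node[[i]], child)
        }
      }
    } else {
      add(if (nzchar(path)) path else "value", node)
    }
  }
  walk(raw, "")

  paths <- sort(ls(acc))
  fields <- vapply(paths, function(p) paste(get(p, envir = acc), collapse = " "),
                   character(1))
  rec <- list(doc_id = doc_id,
              fields = fields,
              catchall = paste(fields, collapse = " "))
  class(rec) <- "MetadataRecord"
  rec
}

# Scalars (including parsed numbers and logicals) rendered as text.
scalarText <- function(v) {
  if (is.character(v)) v else as.character(v)
}

#' @export
print.MetadataRecord <- function(x, ...) {
  cat("<MetadataRecord> ", x$doc_id, ": ", length(x$fields), " fields, ",
      length(tokenize(x$catchall)), " tokens\n", sep = "")
  invisible(x)
}

#' Load a corpus of JSON metadata records
#'
#' Reads either a directory of `*.json` files (one record per file, doc_id
#' from the filename stem unless `id_field` names a metadata field) or a
#' single `*.jsonl` file (one JSON object per line, doc_ids `L000001`, ...
#' unless `id_field` is given). Records that fail to parse are skipped and
#' counted, never aborting the run; a corpus with zero parseable records is
#' an error.
#'
#' @param path Directory of `.json` files or path to a `.jsonl` file.
#' @param id_field Optional name of a top-level field supplying the doc_id.
#' @param quiet Suppress per-file skip messages.
#' @return A `Corpus`: list with `records` (list of [flattenRecord()]
#'   results) and `n_skipped`.
#' @export
loadCorpus <- function(path, id_field = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("corpus path does not exist: ", path)
  units <- list()  # list of (label, raw json string)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
    for (f in files) {
      units[[length(units) + 1L]] <-
        list(label = tools::file_path_sans_ext(basename(f)),
             text = paste(readLines(f, warn = FALSE, encoding = "UTF-8"),
                          collapse = "\n"))
    }
  } else {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    for (i in seq_along(lines)) {
      units[[length(units) + 1L]] <-
        list(label = sprintf("L%06d", i), text = lines[[i]])
    }
  }

  records <- vector("list", length(units))
  ids <- character(length(units))
  n_ok <- 0L; n_skipped <- 0L
  for (u in units) {
    raw <- tryCatch(jsonlite::fromJSON(u$text, simplifyVector = FALSE),
                    error = function(e) e)
    if (inherits(raw, "error")) {
      n_skipped <- n_skipped + 1L
      if (!quiet) message("skipping unparseable record ", u$label, ": ",
                          conditionMessage(raw))
      next
    }
    doc_id <- u$label
    if (!is.null(id_field)) {
      v <- raw[[id_field]]
      if (is.null(v) || !nzchar(as.character(v)[1])) {
        n_skipped <- n_skipped + 1L
        if (!quiet) message("skipping record ", u$label,
                            ": missing id field '", id_field, "'")
        next
      }
      doc_id <- as.character(v)[1]
    }
    n_ok <- n_ok + 1L
    ids[n_ok] <- doc_id
    records[[n_ok]] <- flattenRecord(raw, doc_id)
  }
  if (n_ok == 0L) stop("no parseable records found under ", path)
  ids <- ids[seq_len(n_ok)]
  if (anyDuplicated(ids))
    stop("duplicate doc_ids in corpus: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- list(records = records[seq_len(n_ok)], n_skipped = n_skipped)
  class(out) <- "Corpus"
  out
}

#' @export
print.Corpus <- function(x, ...) {
  cat("<Corpus> ", length(x$records), " records (", x$n_skipped,
      " skipped)\n", sep = "")
  invisible(x)
}
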