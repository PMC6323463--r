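#' Persist an index to a JSON layout
#'
#' Binary-free persistence: the unit ids and token vectors (plus the
#' tokenization settings) are written as JSON; [load_index()] rebuilds the
#' postings from them, so the reloaded index is identical to the original.
#'
#' @param index A `cds_index`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_index <- function(index, path) {
  jsonlite::write_json(
    list(unit_ids = index$unit_ids, tokens = index$tokens,
         stopwords = index$stopwords, stem = index$stem),
    path, auto_unbox = FALSE)
  invisible(path)
}

#' Load an index persisted by [save_index()]
#'
#' @param path JSON path.
#' @return A `cds_index`.
#' @export
load_index <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  toks <- raw$tokens
  if (!is.list(toks)) toks <- as.list(toks)
  toks <- lapply(toks, function(t) as.character(t) %||% character(0))
  units <- data.frame(passage_id = as.character(raw$unit_ids),
                      text = vapply(toks, paste, "", collapse = " "),
                      stringsAsFactors = FALSE)
  # rebuild without re-tokenizing: feed pre-joined tokens through the
  # indexer with no stopwords (they were already applied)
  idx <- build_index(units, stopwords = NULL, stem = FALSE)
  idx$stopwords <- raw$stopwords
  idx$stem <- isTRUE(raw$stem)
  idx
}
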