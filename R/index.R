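#' Build an inverted index over passages or documents
#'
#' Tokenizes each unit (with the configured stopword list and optional
#' stemming) and accumulates postings (term -> unit, tf), document
#' frequencies, collection frequencies, unit lengths and totals. The raw
#' token vectors are retained because pseudo-relevance feedback needs the
#' term content of the top-ranked units.
#'
#' @param units A data.frame with columns `passage_id` (or `doc_id`/`id`)
#'   and `text`; or a list of such records.
#' @param stopwords Stopword vector used at indexing time (default
#'   [cds_stopwords()]). Pass `NULL` to index every token.
#' @param stem Logical, light plural stemming (default `FALSE`).
#' @return An object of class `cds_index`: fields `unit_ids`, `lengths`,
#'   `unit_count`, `total_tokens`, `tokens` (list), and a hashed postings
#'   environment mapping each term to `list(ids, tf, df, cf)` where `ids`
#'   are integer positions into `unit_ids`.
#' @export
build_index <- function(units, stopwords = cds_stopwords(), stem = FALSE) {
  if (is.data.frame(units)) {
    idcol <- intersect(c("passage_id", "doc_id", "id", "unit_id"),
                       names(units))[1]
    if (is.na(idcol)) stop("no id column found in units")
    ids <- as.character(units[[idcol]])
    texts <- as.character(units$text)
  } else {
    ids <- vapply(units, function(u) as.character(u$id %||% u$passage_id),
                  character(1))
    texts <- vapply(units, function(u) as.character(u$text), character(1))
  }
  if (anyDuplicated(ids))
    stop("duplicate unit id: ", ids[duplicated(ids)][1])
  toks <- lapply(texts, tokenize, stopwords = stopwords, stem = stem)
  lens <- lengths(toks)
  post <- new.env(parent = emptyenv(), hash = TRUE, size = 4096L)
  if (sum(lens) > 0) {
    dt <- data.table::data.table(
      term = unlist(toks, use.names = FALSE),
      uid = rep(seq_along(ids), lens))
    agg <- dt[, list(tf = .N), by = c("term", "uid")]
    data.table::setorderv(agg, c("term", "uid"))
    sp <- split(agg, by = "term")
    for (tm in names(sp)) {
      g <- sp[[tm]]
      assign(tm, list(ids = g$uid, tf = g$tf, df = nrow(g), cf = sum(g$tf)),
             envir = post)
    }
  }
  structure(list(unit_ids = ids, lengths = as.integer(lens),
                 unit_count = length(ids), total_tokens = sum(lens),
                 tokens = toks, postings = post,
                 stopwords = stopwords, stem = stem),
            class = "cds_index")
}

#' @export
print.cds_index <- function(x, ...) {
  cat("<cds_index> ", x$unit_count, " units, ", length(ls(x$postings)),
      " terms, ", x$total_tokens, " tokens\n", sep = "")
  invisible(x)
}

# postings lookup; NULL when the term is unseen
index_postings <- function(index, term) {
  get0(term, envir = index$postings, inherits = FALSE)
}

#' Term statistics from an index
#'
#' @param index A `cds_index`.
#' @param terms Character vector of terms.
#' @return data.frame with `term`, `df` (unit frequency) and `cf`
#'   (collection frequency); zeros for unseen terms.
#' @export
term_stats <- function(index, terms) {
  df <- integer(length(terms)); cf <- integer(length(terms))
  for (k in seq_along(terms)) {
    p <- index_postings(index, terms[k])
    if (!is.null(p)) { df[k] <- p$df; cf[k] <- p$cf }
  }
  data.frame(term = terms, df = df, cf = cf, stringsAsFactors = FALSE)
}

#' Read a line-delimited JSON corpus
#'
#' One JSON object per line with at least `passage_id` (or `doc_id`) and
#' `text`; `source_id`, `position`, `sentence_count`, `links` are carried
#' through when present.
#'
#' @param path Path to a JSONL file.
#' @return data.frame with one row per unit.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(seq_along(lines), function(i) {
    tryCatch(jsonlite::fromJSON(lines[i]),
             error = function(e) stop("corpus parse failure at line ", i,
                                      " of '", path, "': ",
                                      conditionMessage(e)))
  })
  grab <- function(r, f, alt = NA) r[[f]] %||% alt
  data.frame(
    passage_id = vapply(recs, function(r)
      as.character(grab(r, "passage_id", grab(r, "doc_id", grab(r, "id")))), ""),
    source_id = vapply(recs, function(r)
      as.character(grab(r, "source_id", "")), ""),
    position = vapply(recs, function(r)
      as.integer(grab(r, "position", NA_integer_)), 1L),
    text = vapply(recs, function(r) as.character(grab(r, "text", "")), ""),
    sentence_count = vapply(recs, function(r)
      as.integer(grab(r, "sentence_count", NA_integer_)), 1L),
    links = vapply(recs, function(r)
      paste(unlist(grab(r, "links", character(0))), collapse = ";"), ""),
    stringsAsFactors = FALSE)
}

#' Write a corpus as line-delimited JSON
#'
#' @param corpus data.frame as produced by [split_passages()] or the
#'   synthetic generator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (k in seq_len(nrow(corpus))) {
    rec <- as.list(corpus[k, , drop = FALSE])
    rec <- lapply(rec, function(v) v[[1]])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con,
               useBytes = TRUE)
  }
  invisible(path)
}
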