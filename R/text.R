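#' Default English stopword list
#'
#' A small, fixed stopword list used when indexing corpora and for the
#' baseline noun-like token passthrough. Deliberately conservative: polarity
#' cues that carry signal for this engine ("normal", "negative", "increased",
#' "high", ...) are *not* stopwords; pure function words are.
#'
#' @return Character vector of lowercase stopwords.
#' @export
cds_stopwords <- function() {
  c("a", "an", "and", "are", "as", "at", "be", "been", "but", "by",
    "for", "from", "had", "has", "have", "he", "her", "his", "if", "in",
    "into", "is", "it", "its", "of", "on", "or", "she", "such", "that",
    "the", "their", "then", "there", "these", "they", "this", "to",
    "was", "were", "which", "while", "will", "with")
}

# Abbreviations that must not terminate a sentence.
.cds_abbrev <- c("e.g", "i.e", "etc", "dr", "fig", "al", "vs", "mr", "mrs",
                 "st", "approx")

#' Tokenize text
#'
#' Lowercases ASCII, strips punctuation except internal hyphens (so the
#' "no-" negation prefix survives as part of a single token, e.g. "no-afp"),
#' and splits on whitespace. Non-Latin characters are kept verbatim so that
#' non-English lexicon surfaces can be matched exactly.
#'
#' @param text Character scalar.
#' @param stopwords Optional character vector of tokens to drop (e.g.
#'   [cds_stopwords()]). `NULL` (default) keeps everything, which is what
#'   concept detection and negation scoping require.
#' @param stem Logical; if `TRUE` a light suffix stripper (plural "s"/"es")
#'   is applied. Off by default so worked oracles are exact.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize <- function(text, stopwords = NULL, stem = FALSE) {
  if (is.null(text) || is.na(text) || !nzchar(text)) return(character(0))
  x <- tolower(text)
  # strip punctuation (unicode-aware) but keep hyphens; then drop hyphens
  # that are not between word characters
  x <- gsub("(*UCP)[^\\w-]+", " ", x, perl = TRUE)
  x <- gsub("_", " ", x, fixed = TRUE)
  x <- gsub("(*UCP)(?<!\\w)-+|-+(?!\\w)", " ", x, perl = TRUE)
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (!is.null(stopwords)) toks <- toks[!(toks %in% stopwords)]
  if (stem && length(toks)) {
    toks <- sub("(..)es$", "\\1", toks)
    toks <- sub("(...)s$", "\\1", toks)
  }
  toks
}

#' Split text into sentences
#'
#' Rule-based splitter: terminal punctuation (.!?) followed by whitespace
#' ends a sentence, unless the preceding word is on a short abbreviation
#' guard list.
#'
#' @param text Character scalar (one paragraph).
#' @return Character vector of sentences, whitespace-trimmed, empty ones
#'   removed.
#' @export
split_sentences <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(character(0))
  x <- gsub("[[:space:]]+", " ", trimws(text))
  # protect abbreviation periods with a control-char placeholder
  for (ab in .cds_abbrev) {
    x <- gsub(paste0("(?i)\\b(", gsub(".", "\\.", ab, fixed = TRUE), ")\\."),
              "\\1\x01", x, perl = TRUE)
  }
  parts <- strsplit(x, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  parts <- gsub("\x01", ".", parts, fixed = TRUE)
  parts <- trimws(parts)
  parts[nzchar(gsub("[.!?[:space:]]+", "", parts))]
}

#' Split source text into passages
#'
#' Paragraphs are delimited by blank lines. A paragraph is admitted as a
#' passage only if it contains at least two sentences; shorter paragraphs
#' (titles, headings) are dropped. Surviving passages are numbered in
#' document order.
#'
#' @param source_text Character scalar holding the full source text.
#' @param source_id Identifier of the source (book, article).
#' @return A `data.frame` with columns `passage_id`, `source_id`, `position`,
#'   `text`, `sentence_count`, `links` (empty here; populated by corpus
#'   readers when link metadata is present).
#' @export
split_passages <- function(source_text, source_id = "src") {
  empty <- data.frame(passage_id = character(0), source_id = character(0),
                      position = integer(0), text = character(0),
                      sentence_count = integer(0), links = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(source_text) || is.na(source_text) || !nzchar(trimws(source_text)))
    return(empty)
  paras <- strsplit(source_text, "\n[[:space:]]*\n")[[1]]
  paras <- trimws(gsub("\n", " ", paras))
  paras <- paras[nzchar(paras)]
  if (!length(paras)) return(empty)
  nsent <- vapply(paras, function(p) length(split_sentences(p)), integer(1),
                  USE.NAMES = FALSE)
  keep <- nsent >= 2L
  paras <- paras[keep]
  nsent <- nsent[keep]
  if (!length(paras)) return(empty)
  data.frame(
    passage_id = sprintf("%s-p%04d", source_id, seq_along(paras)),
    source_id = source_id,
    position = seq_along(paras),
    text = paras,
    sentence_count = nsent,
    links = "",
    stringsAsFactors = FALSE
  )
}

#' Tokenize a text sentence by sentence
#'
#' Splits into sentences, tokenizes each, and returns the flat token vector
#' together with the sentence id of every token — the representation that
#' sentence-bounded negation scoping and concept detection consume.
#'
#' @param text Character scalar.
#' @return List with `tokens` (character) and `sentence` (integer, parallel
#'   to `tokens`).
#' @export
tokenize_sentences <- function(text) {
  sents <- split_sentences(text)
  if (!length(sents)) sents <- text
  toks <- lapply(sents, tokenize)
  n <- lengths(toks)
  list(tokens = unlist(toks, use.names = FALSE) %||% character(0),
       sentence = rep(seq_along(sents), n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
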