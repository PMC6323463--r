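#' Negation trigger lexicon
#'
#' Trigger-based polarity detection in the NegEx tradition, simplified to
#' pre- and post-trigger windows bounded by sentence breaks. The default
#' list is the four laboratory-report cues "no", "not", "negative",
#' "normal"; the latter two also act after the concept ("AFP is normal",
#' "HIV test is negative"), the former two before it ("no anemia").
#'
#' @param pre_triggers Tokens that negate a following concept.
#' @param post_triggers Tokens that negate a preceding concept.
#' @param window Maximum token distance between trigger and concept span
#'   (default 5), never crossing a sentence boundary.
#' @return List of class `cds_neg_lexicon`.
#' @export
negation_lexicon <- function(pre_triggers = c("no", "not", "negative", "normal"),
                             post_triggers = c("negative", "normal"),
                             window = 5L) {
  stopifnot(length(pre_triggers) > 0, length(post_triggers) > 0, window >= 1)
  structure(list(pre_triggers = tolower(pre_triggers),
                 post_triggers = tolower(post_triggers),
                 window = as.integer(window)),
            class = "cds_neg_lexicon")
}

#' Load a negation lexicon from JSON
#'
#' Format: `{"pre_triggers": [...], "post_triggers": [...], "window": 5}`.
#'
#' @param path JSON file path.
#' @return A `cds_neg_lexicon`.
#' @export
load_negation_lexicon <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  negation_lexicon(raw$pre_triggers, raw$post_triggers,
                   raw$window %||% 5L)
}

#' Assign polarity to concept mentions
#'
#' A mention is `negated` when a pre-trigger occurs within `window` tokens
#' before its span, or a post-trigger within `window` tokens after it, in
#' the same sentence; otherwise it is `affirmed`.
#'
#' @param tokens Token vector the mention spans index into.
#' @param mentions Mention data.frame from [detect_and_translate()].
#' @param lexicon A [negation_lexicon()].
#' @param sentence Optional integer vector, one sentence id per token
#'   (from [tokenize_sentences()]); if `NULL` the whole sequence is one
#'   sentence.
#' @return `mentions` with `polarity` set to `"negated"`/`"affirmed"`.
#' @export
detect_polarity <- function(tokens, mentions, lexicon = negation_lexicon(),
                            sentence = NULL) {
  if (!nrow(mentions)) return(mentions)
  n <- length(tokens)
  if (is.null(sentence)) sentence <- rep(1L, n)
  tokens <- tolower(tokens)
  for (k in seq_len(nrow(mentions))) {
    s <- mentions$start[k]; e <- mentions$end[k]
    if (s < 0 || e > n || s >= e)
      stop("mention '", mentions$surface[k], "' has span [", s, ",", e,
           ") outside the ", n, "-token sequence")
    sent <- sentence[s + 1L]
    lo <- max(1L, s + 1L - lexicon$window)
    before <- which(seq_len(n) >= lo & seq_len(n) <= s &
                      sentence == sent)
    hi <- min(n, e + lexicon$window)
    after <- which(seq_len(n) >= e + 1L & seq_len(n) <= hi &
                     sentence == sent)
    neg <- any(tokens[before] %in% lexicon$pre_triggers) ||
      any(tokens[after] %in% lexicon$post_triggers)
    mentions$polarity[k] <- if (neg) "negated" else "affirmed"
  }
  mentions
}

#' Rewrite synonyms of negated concepts with the "no-" prefix
#'
#' Synonym-origin query terms whose source concept was detected as negated
#' are rewritten to `"no-" + term` and flagged. Original terms are never
#' modified (the raw query intent is preserved), nor are PRF-origin terms.
#' Idempotent: already-prefixed terms are left alone.
#'
#' @param query A `cds_query` produced after synonym expansion.
#' @param mentions Polarity-annotated mentions ([detect_polarity()]).
#' @return The rewritten `cds_query`.
#' @export
apply_no_prefix <- function(query, mentions) {
  if (!nrow(query) || !nrow(mentions)) return(query)
  negated <- mentions$instance_id[mentions$polarity == "negated"]
  hit <- query$origin == "synonym" & !query$neg_prefixed &
    !is.na(query$source_concept) & query$source_concept %in% negated
  query$term[hit] <- paste0("no-", query$term[hit])
  query$neg_prefixed[hit] <- TRUE
  query
}

#' Query abnormality classification
#'
#' A query is abnormal (`abn = 1`) when its affirmed concept mentions are
#' at least as many as its negated ones; otherwise normal (`abn = 0`).
#' The inclusive inequality means a query with no detected concepts is
#' classified abnormal (0 >= 0), a documented literal reading.
#'
#' @param mentions Polarity-annotated query mentions.
#' @return List `affirmed`, `negated`, `abn`.
#' @export
query_abnormality <- function(mentions) {
  aff <- sum(mentions$polarity == "affirmed")
  neg <- sum(mentions$polarity == "negated")
  list(affirmed = aff, negated = neg, abn = as.integer(aff >= neg))
}

#' Polarity profile of a passage
#'
#' Detects concept mentions in the passage with the same detector used for
#' queries, assigns polarity sentence-by-sentence, and tallies counts.
#' Repeated concepts count once per mention.
#'
#' @param text Passage text.
#' @param ontology A `cds_ontology`.
#' @param lexicon A [negation_lexicon()].
#' @return List `affirmed`, `negated` (no `abn`: the classification only
#'   applies to queries).
#' @export
passage_polarity_counts <- function(text, ontology,
                                    lexicon = negation_lexicon()) {
  ts <- tokenize_sentences(text)
  if (!length(ts$tokens)) return(list(affirmed = 0L, negated = 0L))
  mentions <- detect_and_translate(ts$tokens, ontology)
  if (!nrow(mentions)) return(list(affirmed = 0L, negated = 0L))
  mentions <- detect_polarity(ts$tokens, mentions, lexicon,
                              sentence = ts$sentence)
  list(affirmed = sum(mentions$polarity == "affirmed"),
       negated = sum(mentions$polarity == "negated"))
}
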