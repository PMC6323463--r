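#' Pipeline configuration (retrieval feature ablation)
#'
#' The five named configurations form a nested ladder of features:
#' \tabular{lccccc}{
#'   \tab concept detection \tab synonyms \tab local PRF \tab global PRF
#'     \tab negation \cr
#'   baseline \tab (tokens) \tab on \tab - \tab - \tab - \cr
#'   umlse    \tab ontology \tab on \tab - \tab - \tab - \cr
#'   lprf     \tab ontology \tab on \tab on \tab - \tab - \cr
#'   gprf     \tab ontology \tab on \tab on \tab on \tab - \cr
#'   gprf-neg \tab ontology \tab on \tab on \tab on \tab on \cr
#' }
#' Global PRF requires local PRF; negation requires global PRF. A `custom`
#' preset lifts the nesting restriction.
#'
#' @param preset One of `"baseline"`, `"umlse"`, `"lprf"`, `"gprf"`,
#'   `"gprf-neg"`, `"custom"`.
#' @param use_ontology_cd,use_synonym_expansion,use_local_prf,use_global_prf,use_negation
#'   Feature flags; defaults follow the preset.
#' @param params [model_params()]; `prf` [prf_config()]; `fusion`
#'   [fusion_config()]; `neg_lexicon` [negation_lexicon()]; `synonym_weight`
#'   weight for synonym expansion terms (default 0.5).
#' @param params,prf,fusion,neg_lexicon,synonym_weight Component settings.
#' @return List of class `cds_pipeline_config`.
#' @export
pipeline_config <- function(preset = c("gprf-neg", "baseline", "umlse",
                                       "lprf", "gprf", "custom"),
                            use_ontology_cd = NULL,
                            use_synonym_expansion = NULL,
                            use_local_prf = NULL, use_global_prf = NULL,
                            use_negation = NULL,
                            params = model_params(), prf = prf_config(),
                            fusion = fusion_config(),
                            neg_lexicon = negation_lexicon(),
                            synonym_weight = 0.5) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    "baseline" = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    "umlse"    = c(TRUE,  TRUE, FALSE, FALSE, FALSE),
    "lprf"     = c(TRUE,  TRUE, TRUE,  FALSE, FALSE),
    "gprf"     = c(TRUE,  TRUE, TRUE,  TRUE,  FALSE),
    "gprf-neg" = c(TRUE,  TRUE, TRUE,  TRUE,  TRUE),
    "custom"   = c(TRUE,  TRUE, TRUE,  TRUE,  TRUE))
  flags <- list(use_ontology_cd = use_ontology_cd %||% defaults[1],
                use_synonym_expansion = use_synonym_expansion %||% defaults[2],
                use_local_prf = use_local_prf %||% defaults[3],
                use_global_prf = use_global_prf %||% defaults[4],
                use_negation = use_negation %||% defaults[5])
  if (preset != "custom") {
    if (flags$use_global_prf && !flags$use_local_prf)
      stop("global PRF requires local PRF (feature nesting)")
    if (flags$use_negation && !flags$use_global_prf)
      stop("negation re-ranking requires global PRF (feature nesting)")
  }
  structure(c(flags, list(preset = preset, params = params, prf = prf,
                          fusion = fusion, neg_lexicon = neg_lexicon,
                          synonym_weight = synonym_weight)),
            class = "cds_pipeline_config")
}

#' Build a search engine over a collection
#'
#' Indexes the passage corpus (and, when present, the document corpus for
#' global feedback), and precomputes the per-passage polarity profiles the
#' negation boost consumes.
#'
#' @param ontology A `cds_ontology`.
#' @param passages Passage data.frame (columns `passage_id`, `text`).
#' @param documents Optional document data.frame for global PRF.
#' @param stopwords Indexing stopword list.
#' @param neg_lexicon A [negation_lexicon()] for passage profiling.
#' @param profile_passages Compute polarity profiles (default `TRUE`; the
#'   boost treats missing profiles as mention-free).
#' @return List of class `cds_engine`.
#' @export
cds_engine <- function(ontology, passages, documents = NULL,
                       stopwords = cds_stopwords(),
                       neg_lexicon = negation_lexicon(),
                       profile_passages = TRUE) {
  pidx <- build_index(passages, stopwords = stopwords)
  didx <- if (!is.null(documents)) build_index(documents,
                                               stopwords = stopwords)
  profiles <- new.env(parent = emptyenv(), hash = TRUE)
  if (profile_passages) {
    for (k in seq_len(nrow(passages))) {
      assign(passages$passage_id[k],
             passage_polarity_counts(passages$text[k], ontology,
                                     neg_lexicon),
             envir = profiles)
    }
  }
  structure(list(ontology = ontology, passage_index = pidx,
                 doc_index = didx, profiles = profiles,
                 stopwords = stopwords,
                 provider = ontology_synonym_provider(ontology)),
            class = "cds_engine")
}

# fused-model retrieval used both for feedback and for the final list
fused_retrieval <- function(query, index, params, fusion) {
  pm <- list(tfidf = score_passages(query, index, "tfidf", params),
             bm25 = score_passages(query, index, "bm25", params),
             lm = score_passages(query, index, "lm", params))
  normalize_and_fuse(pm, fusion)
}

#' Run one query through the retrieval pipeline
#'
#' Stages, each gated by the pipeline config: sentence-aware tokenization;
#' concept detection and translation through the ontology (or a
#' stopword-filtered token passthrough for the baseline); weighted synonym
#' expansion; polarity detection with "no-" prefix rewriting of negated
#' concepts' synonyms; local feedback on the passage index; global feedback
#' on the document index fused by lambda; top-m reformulation; scoring under
#' the three retrieval models; min-max fusion; negation differential boost;
#' final ranking.
#'
#' @param query_text Free-text case report.
#' @param engine A [cds_engine()].
#' @param config A [pipeline_config()].
#' @param verbose Log one line per stage.
#' @return List of class `cds_result`: `ranked` (data.frame `passage_id`,
#'   `score`, `rank`), `query` (final `cds_query`), `mentions`,
#'   `query_profile`, `stages` (named list of intermediate queries).
#' @export
run_search <- function(query_text, engine, config = pipeline_config(),
                       verbose = FALSE) {
  ts <- tokenize_sentences(query_text)
  stages <- list()
  logmsg <- function(stage, q) {
    if (verbose) {
      top <- utils::head(q$term[order(-q$weight)], 5)
      message(sprintf("[%s] %d terms: %s", stage, nrow(q),
                      paste(top, collapse = ", ")))
    }
  }
  mentions <- NULL
  if (config$use_ontology_cd) {
    mentions <- detect_and_translate(ts$tokens, engine$ontology)
    if (nrow(mentions)) {
      query <- weighted_query(unique(mentions$representative), 1, "original")
      query$source_concept <- mentions$instance_id[
        match(query$term, mentions$representative)]
    } else {
      warning("no concepts detected; falling back to raw tokens")
      query <- weighted_query(unique(tokenize(query_text,
                                              stopwords = engine$stopwords)),
                              1, "original")
      mentions <- NULL
    }
  } else {
    toks <- unique(tokenize(query_text, stopwords = engine$stopwords))
    if (!length(toks)) toks <- unique(ts$tokens)
    query <- weighted_query(toks, 1, "original")
  }
  stages$concepts <- query; logmsg("concepts", query)

  if (config$use_synonym_expansion && !is.null(mentions) && nrow(mentions)) {
    query <- expand_synonyms(mentions, engine$provider,
                             weight = config$synonym_weight)
    stages$synonyms <- query; logmsg("synonyms", query)
  }

  query_profile <- list(affirmed = 0L, negated = 0L, abn = 1L)
  if (config$use_negation && !is.null(mentions) && nrow(mentions)) {
    mentions <- detect_polarity(ts$tokens, mentions, config$neg_lexicon,
                                sentence = ts$sentence)
    query <- apply_no_prefix(query, mentions)
    query_profile <- query_abnormality(mentions)
    stages$negation <- query; logmsg("negation", query)
  }

  if (config$use_local_prf) {
    fb <- retrieve_topk(
      fused_retrieval(query, engine$passage_index, config$params,
                      config$fusion),
      config$prf$k, positive_only = TRUE)
    local_tab <- prf_term_weights(query, fb$unit_id, engine$passage_index,
                                  config$prf)
    global_tab <- NULL
    if (config$use_global_prf && !is.null(engine$doc_index)) {
      fbg <- retrieve_topk(
        fused_retrieval(query, engine$doc_index, config$params,
                        config$fusion),
        config$prf$k, positive_only = TRUE)
      global_tab <- prf_term_weights(query, fbg$unit_id, engine$doc_index,
                                     config$prf)
    }
    fused_tab <- fuse_prf(local_tab, global_tab, config$prf)
    query <- expand_query(query, fused_tab, config$prf)
    stages$prf <- query; logmsg("prf", query)
  }

  per_model <- list(
    tfidf = score_passages(query, engine$passage_index, "tfidf",
                           config$params),
    bm25 = score_passages(query, engine$passage_index, "bm25",
                          config$params),
    lm = score_passages(query, engine$passage_index, "lm", config$params))
  fused <- normalize_and_fuse(per_model, config$fusion)

  boosted <- fused
  if (config$use_negation && query_profile$abn == 1L)
    boosted <- negation_boost(fused, engine$profiles, query_profile,
                              config$fusion)
  ranked <- rank_final(boosted, config$fusion)
  structure(list(ranked = ranked, query = query, mentions = mentions,
                 query_profile = query_profile, stages = stages),
            class = "cds_result")
}

#' Run a query batch and assemble a TREC run
#'
#' @param queries data.frame with `query_id` and `text`.
#' @param engine A [cds_engine()].
#' @param config A [pipeline_config()].
#' @param tag Run tag written into the run records (default: the preset).
#' @return Run data.frame (`query_id`, `passage_id`, `rank`, `score`,
#'   `tag`), suitable for [write_run()] and [evaluate_run()].
#' @export
batch_run <- function(queries, engine, config = pipeline_config(),
                      tag = config$preset) {
  out <- vector("list", nrow(queries))
  for (k in seq_len(nrow(queries))) {
    res <- suppressWarnings(run_search(queries$text[k], engine, config))
    if (!nrow(res$ranked)) next
    out[[k]] <- data.frame(query_id = queries$query_id[k],
                           passage_id = res$ranked$passage_id,
                           rank = res$ranked$rank,
                           score = res$ranked$score, tag = tag,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
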