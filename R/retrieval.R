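#' Retrieval model parameters
#'
#' @param mu Dirichlet prior for the language model (default 2500).
#' @param bm25_k1 BM25 term-frequency saturation (default 1.2).
#' @param bm25_b BM25 length normalization in `[0, 1]` (default 0.75).
#' @param tfidf_variant Tag recording the TF-IDF formula in use; only
#'   `"lnc-log10"` is implemented: `(1 + ln tf) * log10(C / df)`.
#' @return A list of class `cds_model_params`.
#' @export
model_params <- function(mu = 2500, bm25_k1 = 1.2, bm25_b = 0.75,
                         tfidf_variant = "lnc-log10") {
  stopifnot(mu > 0, bm25_k1 >= 0, bm25_b >= 0, bm25_b <= 1)
  structure(list(mu = mu, bm25_k1 = bm25_k1, bm25_b = bm25_b,
                 tfidf_variant = tfidf_variant),
            class = "cds_model_params")
}

#' Score all index units for a weighted query
#'
#' Three models are available, each linear in the query term weights (a
#' term's score contribution is multiplied by its query weight):
#' \describe{
#'   \item{tfidf}{`sum_t w_t * (1 + ln tf) * log10(C / df_t)`; 0 for units
#'     sharing no term with the query.}
#'   \item{bm25}{Robertson BM25 with the non-negative (Lucene-style)
#'     idf `ln(1 + (C - df + 0.5) / (df + 0.5))`, `k1`/`b` from `params`.}
#'   \item{lm}{Dirichlet-smoothed query log-likelihood
#'     `sum_t w_t * ln((tf + mu * cf_t / T) / (len + mu))`, defined (and
#'     <= 0) for every unit. Query terms absent from the whole collection
#'     are skipped, the standard convention for zero collection frequency.}
#' }
#' Terms carrying the "no-" prefix simply fail to match any unprefixed index
#' term, which is the intended retrieval effect of the prefix rewrite.
#'
#' @param query A `cds_query` (see [weighted_query()]).
#' @param index A `cds_index`.
#' @param model `"tfidf"`, `"bm25"` or `"lm"`.
#' @param params A [model_params()] list.
#' @return Named numeric vector of scores over all units (names =
#'   `unit_ids`).
#' @export
score_passages <- function(query, index, model = c("tfidf", "bm25", "lm"),
                           params = model_params()) {
  model <- match.arg(model)
  if (index$unit_count == 0) return(stats::setNames(numeric(0), character(0)))
  scores <- numeric(index$unit_count)
  C <- index$unit_count
  avgdl <- index$total_tokens / max(C, 1)
  terms <- query$term
  w <- query$weight
  for (k in seq_along(terms)) {
    if (w[k] == 0) next
    p <- index_postings(index, terms[k])
    if (model == "lm") {
      if (is.null(p)) next                       # cf = 0: term contributes nothing
      pc <- p$cf / index$total_tokens
      # background part for every unit, then correct units containing the term
      scores <- scores + w[k] * (log(params$mu * pc) - log(index$lengths + params$mu))
      scores[p$ids] <- scores[p$ids] +
        w[k] * (log(p$tf + params$mu * pc) - log(params$mu * pc))
    } else if (model == "tfidf") {
      if (is.null(p) || p$df == 0) next
      idf <- log10(C / p$df)
      scores[p$ids] <- scores[p$ids] + w[k] * (1 + log(p$tf)) * idf
    } else { # bm25
      if (is.null(p) || p$df == 0) next
      idf <- log(1 + (C - p$df + 0.5) / (p$df + 0.5))
      denom <- p$tf + params$bm25_k1 *
        (1 - params$bm25_b + params$bm25_b * index$lengths[p$ids] / avgdl)
      scores[p$ids] <- scores[p$ids] +
        w[k] * idf * (p$tf * (params$bm25_k1 + 1)) / denom
    }
  }
  stats::setNames(scores, index$unit_ids)
}

#' Top-k units from a score mapping
#'
#' Descending by score with ties broken by ascending unit id. For the sparse
#' models (tfidf, bm25) only units with strictly positive scores are
#' candidates; the language model defines a score for every unit.
#'
#' @param scores Named numeric vector (unit id -> score).
#' @param k Number of results (>= 1).
#' @param positive_only Drop non-positive scores first (use for tfidf/bm25
#'   and fused scores).
#' @return data.frame `unit_id`, `score`, ordered, at most `k` rows.
#' @export
retrieve_topk <- function(scores, k, positive_only = FALSE) {
  stopifnot(k >= 1)
  if (positive_only) scores <- scores[scores > 0]
  if (!length(scores))
    return(data.frame(unit_id = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  ord <- order(-scores, names(scores), method = "radix")
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(unit_id = names(scores)[ord], score = unname(scores[ord]),
             stringsAsFactors = FALSE)
}
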