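#' Score fusion and boosting configuration
#'
#' @param n_models Number of retrieval models fused (default 3).
#' @param m_retrieved Per-model candidate pool depth M (default 100).
#' @param gamma Negation boost factor (default 2.0).
#' @param output_depth Final run-list length (default 500).
#' @return List of class `cds_fusion_config`.
#' @export
fusion_config <- function(n_models = 3, m_retrieved = 100, gamma = 2.0,
                          output_depth = 500) {
  stopifnot(n_models >= 1, m_retrieved >= 1, gamma >= 0, output_depth >= 1)
  structure(list(n_models = n_models, m_retrieved = m_retrieved,
                 gamma = gamma, output_depth = output_depth),
            class = "cds_fusion_config")
}

#' Min-max normalize per-model scores and fuse
#'
#' The candidate pool is the union of each model's top-M units (positive
#' scores only for the sparse models). Per model, scores over the pool are
#' min-max normalized to `[0, 1]`; a unit a model did not score is imputed
#' with that model's pool minimum (normalizing to 0, so fusion never
#' rewards absence); a degenerate model (max = min over the pool)
#' contributes 0 throughout. The fused score of a unit is its summed
#' normalized score divided by the pool total, so fused scores form a
#' distribution summing to 1; if every model is degenerate the fused
#' distribution is uniform.
#'
#' @param per_model_scores Named list `model -> named numeric vector` of raw
#'   scores (names are unit ids).
#' @param config A [fusion_config()].
#' @param sparse_models Models whose zero scores mean "no match" and are
#'   excluded from the pool (default `c("tfidf", "bm25")`).
#' @return Named numeric vector of fused scores over the pool.
#' @export
normalize_and_fuse <- function(per_model_scores, config = fusion_config(),
                               sparse_models = c("tfidf", "bm25")) {
  pool <- character(0)
  for (mn in names(per_model_scores)) {
    top <- retrieve_topk(per_model_scores[[mn]], config$m_retrieved,
                         positive_only = mn %in% sparse_models)
    pool <- union(pool, top$unit_id)
  }
  if (!length(pool)) return(stats::setNames(numeric(0), character(0)))
  pool <- sort(pool)
  acc <- numeric(length(pool))
  for (mn in names(per_model_scores)) {
    s <- per_model_scores[[mn]][pool]
    if (anyNA(s)) s[is.na(s)] <- min(s, na.rm = TRUE)
    rng <- range(s)
    if (rng[2] > rng[1]) acc <- acc + (s - rng[1]) / (rng[2] - rng[1])
  }
  tot <- sum(acc)
  if (tot > 0) acc <- acc / tot else acc <- rep(1 / length(pool), length(pool))
  stats::setNames(acc, pool)
}

#' Negation differential boost
#'
#' For an abnormal query (`abn = 1`) every pooled passage receives
#' `gamma * (1 + A_i / (A_i + N_i))`, where `A_i`/`N_i` are its affirmed and
#' negated concept-mention counts; a passage with no mentions takes the
#' fraction as 0 and still receives `gamma`. For a normal query
#' (`abn = 0`) scores pass through unchanged. Passages rich in affirmed
#' (abnormality-describing) concepts thus gain up to `2 * gamma`.
#'
#' @param fused Named fused score vector from [normalize_and_fuse()].
#' @param profiles List or environment mapping unit id to a profile with
#'   `affirmed`/`negated` counts (see [passage_polarity_counts()]); missing
#'   ids count as (0, 0).
#' @param query_profile Result of [query_abnormality()] (needs `$abn`).
#' @param config A [fusion_config()] supplying `gamma`.
#' @return Named numeric vector of boosted scores.
#' @export
negation_boost <- function(fused, profiles, query_profile,
                           config = fusion_config()) {
  stopifnot(query_profile$abn %in% c(0L, 1L))
  if (query_profile$abn == 0 || !length(fused)) return(fused)
  getp <- function(id) {
    p <- if (is.environment(profiles)) get0(id, envir = profiles,
                                            inherits = FALSE) else profiles[[id]]
    if (is.null(p)) list(affirmed = 0L, negated = 0L) else p
  }
  add <- vapply(names(fused), function(id) {
    p <- getp(id)
    tot <- p$affirmed + p$negated
    frac <- if (tot > 0) p$affirmed / tot else 0
    config$gamma * (1 + frac)
  }, numeric(1))
  fused + add
}

#' Final ranking
#'
#' Orders descending by score, ties by ascending passage id, and truncates
#' to the configured output depth.
#'
#' @param boosted Named numeric score vector.
#' @param config A [fusion_config()] supplying `output_depth`.
#' @return data.frame `passage_id`, `score`, `rank`.
#' @export
rank_final <- function(boosted, config = fusion_config()) {
  out <- retrieve_topk(boosted, config$output_depth)
  names(out)[1] <- "passage_id"
  out$rank <- seq_len(nrow(out))
  out
}
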