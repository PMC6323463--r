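#' Pseudo-relevance feedback configuration
#'
#' @param alpha Weight of the query-membership term-frequency component
#'   (default 2).
#' @param beta Weight of the inverse-passage-frequency component
#'   (default 0.75).
#' @param k Feedback depth: number of top-ranked units mined (default 5).
#' @param lam Local/global mixing weight lambda in `[0, 1]` (default 0.65);
#'   the fused weight is `lam * S_local + (1 - lam) * S_global`.
#' @param m Number of expansion terms appended to the query (default 35).
#' @return List of class `cds_prf_config`.
#' @export
prf_config <- function(alpha = 2, beta = 0.75, k = 5, lam = 0.65, m = 35) {
  stopifnot(k >= 1, lam >= 0, lam <= 1, m >= 0, alpha >= 0, beta >= 0)
  structure(list(alpha = alpha, beta = beta, k = k, lam = lam, m = m),
            class = "cds_prf_config")
}

#' Feedback term weights over the top-k retrieved units
#'
#' Builds the root set (query terms united with all terms of the feedback
#' units) and assigns every term `t` a raw weight
#' \deqn{S_t(t) = \alpha \, I_Q(t) \, tf_t / N +
#'       (\beta / k) \sum_{i=1}^{k} I_{P_i}(t)\, \mathrm{ipf}_t}
#' damped to \eqn{S_l(t) = \log_{10}(10 + S_t(t))}, so a term with no
#' support anchors at exactly 1. Conventions: `tf_t` is the frequency of `t`
#' in the concatenation of the top-k units; `N` their total token count;
#' `I_Q` indicates query membership; `I_Pi` indicates presence in feedback
#' unit `i`; and `ipf_t = log10((C + 1) / df_t)` is the inverse
#' passage/document frequency of `t` in the *corpus* the feedback was drawn
#' from (`C` units, `df_t` containing `t`). Corpus-level ipf is what lets a
#' term pervading all k feedback units — the classic latent associate —
#' outrank incidental co-occurrences.
#'
#' @param query A `cds_query`; terms flagged `neg_prefixed` still count as
#'   query members.
#' @param feedback_ids Character ids of the top-k units (ordered), from
#'   [retrieve_topk()] on `index`.
#' @param index The `cds_index` the feedback came from (supplies both the
#'   unit token vectors and the corpus df for ipf).
#' @param config A [prf_config()].
#' @return data.frame of class `cds_prf_table`: `term`, `tf`, `pf` (number
#'   of feedback units containing the term), `in_query`, `ipf`, `s_raw`
#'   (`S_t`), `s` (`S_l`). With an empty feedback set all terms get
#'   `s_raw = 0`, `s = 1` (degenerate case).
#' @export
prf_term_weights <- function(query, feedback_ids, index,
                             config = prf_config()) {
  qterms <- unique(query$term)
  idx <- match(feedback_ids, index$unit_ids)
  idx <- idx[!is.na(idx)]
  toks <- if (length(idx)) index$tokens[idx] else list()
  k_eff <- max(length(idx), 1L)
  all_toks <- unlist(toks, use.names = FALSE)
  N <- length(all_toks)
  terms <- unique(c(qterms, all_toks))
  if (!length(terms)) terms <- character(0)
  tf <- if (N) {
    tab <- table(all_toks)
    as.numeric(tab[terms])
  } else numeric(length(terms))
  tf[is.na(tf)] <- 0
  pf <- numeric(length(terms))
  if (length(toks) && length(terms)) {
    mat <- vapply(toks, function(tt) terms %in% tt, logical(length(terms)))
    pf <- if (length(terms) == 1L) sum(mat) else rowSums(mat)
  }
  dfv <- term_stats(index, terms)$df
  ipf <- ifelse(dfv > 0, log10((index$unit_count + 1) / dfv), 0)
  in_q <- terms %in% qterms
  s_raw <- numeric(length(terms))
  if (N > 0)
    s_raw <- config$alpha * as.numeric(in_q) * tf / N
  s_raw <- s_raw + (config$beta / k_eff) * pf * ipf
  out <- data.frame(term = terms, tf = tf, pf = pf, in_query = in_q,
                    ipf = ipf, s_raw = s_raw, s = log10(10 + s_raw),
                    stringsAsFactors = FALSE)
  class(out) <- c("cds_prf_table", "data.frame")
  out
}

#' Fuse local and global feedback weight tables
#'
#' `S_prf(t) = lam * S_l(t) + (1 - lam) * S_g(t)` over the union of terms; a
#' term missing from one table takes that table's degenerate value 1
#' (i.e. raw weight 0), so the fusion is total.
#'
#' @param local `cds_prf_table` from the passage corpus.
#' @param global_ `cds_prf_table` from the document corpus, or `NULL` to
#'   use the local table alone (equivalent to `lam = 1`).
#' @param config A [prf_config()].
#' @return data.frame `term`, `s_local`, `s_global`, `s_prf`, `in_query`.
#' @export
fuse_prf <- function(local, global_ = NULL, config = prf_config()) {
  if (is.null(global_)) {
    out <- data.frame(term = local$term, s_local = local$s, s_global = 1,
                      s_prf = local$s, in_query = local$in_query,
                      stringsAsFactors = FALSE)
    return(out)
  }
  terms <- union(local$term, global_$term)
  sl <- local$s[match(terms, local$term)];  sl[is.na(sl)] <- 1
  sg <- global_$s[match(terms, global_$term)]; sg[is.na(sg)] <- 1
  in_q <- terms %in% c(local$term[local$in_query],
                       global_$term[global_$in_query])
  data.frame(term = terms, s_local = sl, s_global = sg,
             s_prf = config$lam * sl + (1 - config$lam) * sg,
             in_query = in_q, stringsAsFactors = FALSE)
}

#' Reformulate the query with top-m feedback terms
#'
#' Candidate terms are those not already in the query, ranked by fused
#' weight `s_prf` (descending, ties by ascending term). The top `m` are
#' appended with origin `"prf"` and weight `s_prf / max(s_prf)` over the
#' appended set, so added weights lie in `(0, 1]`. Original terms are
#' preserved untouched.
#'
#' @param query A `cds_query`.
#' @param fused Fusion table from [fuse_prf()].
#' @param config A [prf_config()]; `m = 0` returns the query unchanged.
#' @return The expanded `cds_query`.
#' @export
expand_query <- function(query, fused, config = prf_config()) {
  if (config$m == 0 || !nrow(fused)) return(query)
  cand <- fused[!(fused$term %in% query$term), , drop = FALSE]
  if (!nrow(cand)) return(query)
  ord <- order(-cand$s_prf, cand$term, method = "radix")
  cand <- cand[ord[seq_len(min(config$m, nrow(cand)))], , drop = FALSE]
  wmax <- max(cand$s_prf)
  w <- if (wmax > 0) cand$s_prf / wmax else rep(1, nrow(cand))
  as_cds_query(rbind(query, weighted_query(cand$term, w, origin = "prf")))
}
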