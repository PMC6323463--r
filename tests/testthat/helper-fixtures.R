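# shared fixtures built in code

fixture_ontology_path <- function() {
  system.file("extdata", "lab_ontology.json", package = "cdsearch")
}

fixture_ontology <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_ontology(fixture_ontology_path())
    cache
  }
})

# a 5-unit hand corpus used by the scorer oracle tests
hand_units <- function() {
  data.frame(
    passage_id = c("u1", "u2", "u3", "u4", "u5"),
    text = c("a a b", "b c", "a c c d", "d d d", "e a b c"),
    stringsAsFactors = FALSE)
}

hand_index <- function() build_index(hand_units(), stopwords = NULL)

# direct-arithmetic scorer oracles, independent of the package internals:
# they recount tf/df/cf from the raw token lists
oracle_scores <- function(units, query_terms, query_weights, model,
                          mu = 2500, k1 = 1.2, b = 0.75) {
  toks <- lapply(units$text, function(t) strsplit(t, " ", fixed = TRUE)[[1]])
  C <- nrow(units)
  lens <- lengths(toks)
  avgdl <- mean(lens)
  total <- sum(lens)
  out <- numeric(C)
  for (i in seq_len(C)) {
    s <- 0
    for (j in seq_along(query_terms)) {
      term <- query_terms[j]; w <- query_weights[j]
      tf <- sum(toks[[i]] == term)
      df <- sum(vapply(toks, function(tt) term %in% tt, logical(1)))
      cf <- sum(vapply(toks, function(tt) sum(tt == term), numeric(1)))
      if (model == "tfidf") {
        if (tf > 0 && df > 0) s <- s + w * (1 + log(tf)) * log10(C / df)
      } else if (model == "bm25") {
        if (tf > 0 && df > 0) {
          idf <- log(1 + (C - df + 0.5) / (df + 0.5))
          s <- s + w * idf * tf * (k1 + 1) /
            (tf + k1 * (1 - b + b * lens[i] / avgdl))
        }
      } else if (model == "lm") {
        if (cf > 0) {
          pc <- cf / total
          s <- s + w * log((tf + mu * pc) / (lens[i] + mu))
        }
      }
    }
    out[i] <- s
  }
  stats::setNames(out, units$passage_id)
}

# brute-force metric oracles operating on plain vectors
oracle_p_at_n <- function(ranked, relevant, n) {
  hits <- 0
  for (i in seq_len(n)) {
    if (i <= length(ranked) && ranked[i] %in% relevant) hits <- hits + 1
  }
  hits / n
}

oracle_rprec <- function(ranked, relevant) {
  R <- length(relevant)
  hits <- 0
  for (i in seq_len(min(R, length(ranked)))) {
    if (ranked[i] %in% relevant) hits <- hits + 1
  }
  hits / R
}

oracle_ndcg <- function(ranked, relevant, n) {
  if (!length(relevant)) return(0)
  dcg <- 0
  for (p in seq_len(min(n, length(ranked)))) {
    g <- as.numeric(ranked[p] %in% relevant)
    dcg <- dcg + if (p == 1) g else g / log2(p)
  }
  idcg <- 0
  for (p in seq_len(min(n, length(relevant)))) {
    idcg <- idcg + if (p == 1) 1 else 1 / log2(p)
  }
  dcg / idcg
}

oracle_rr <- function(ranked, relevant) {
  for (i in seq_along(ranked)) if (ranked[i] %in% relevant) return(1 / i)
  0
}

# tiny deterministic collection for pipeline tests (fast)
small_sim_config <- function(seed = 1) {
  sim_config(seed = seed, n_concepts = 6, n_passages = 300,
             n_documents = 500, relevance_rate = 0.04,
             vocabulary_size = 150)
}
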