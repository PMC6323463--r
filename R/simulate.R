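#' Synthetic collection configuration
#'
#' Describes the generated world: a laboratory-test vocabulary with
#' multilingual synonyms, a passage corpus in which on-topic passages phrase
#' a concept either as an abnormal finding (affirmed, e.g. "X has been
#' increased") or a normal one (carrying a negation trigger, e.g. "X is
#' normal"), a larger document corpus in which each test co-occurs with its
#' linked disease (the latent associate a feedback step can discover), and
#' a query set split between normal and abnormal phrasings.
#'
#' @param seed Integer seed; identical seed + config reproduce the
#'   collection exactly.
#' @param n_concepts Number of Test concepts (= number of queries).
#' @param synonyms_per_concept Synonyms per Test concept, including one
#'   ASCII-safe surrogate "Korean" surface (prefix `kx`).
#' @param n_passages,n_documents Corpus sizes.
#' @param sentences_range Min/max sentences per passage.
#' @param tokens_per_sentence Background sentence length.
#' @param relevance_rate Fraction of passages on-topic per concept.
#' @param abnormal_fraction Fraction of queries phrased as abnormal cases.
#' @param abnormal_passage_fraction Fraction of on-topic passages phrased
#'   as abnormal findings.
#' @param latent_cooccurrence_rate Probability that an abnormal-phrased
#'   on-topic passage or a relevant document also mentions the concept's
#'   linked disease term.
#' @param latent_cooccurrence_rate_normal Same for normal-phrased on-topic
#'   passages. Kept low by default: textbook discussion of a disease
#'   accompanies descriptions of the abnormal finding, not statements that
#'   a value is normal. This asymmetry is what makes the mined latent term
#'   informative about relevance rather than merely about topicality.
#' @param latent_only_fraction Size of the disease-only passage set per
#'   concept, as a fraction of the on-topic set; these passages never
#'   mention the test itself and are reachable only through feedback
#'   expansion.
#' @param negation_trigger_rate Probability that a normal-phrased concept
#'   sentence carries an explicit negation trigger.
#' @param synonym_mention_rate Probability an on-topic passage refers to the
#'   concept by a synonym rather than the representative term.
#' @param query_korean_rate Probability a query uses the surrogate Korean
#'   surface (resolvable only through the ontology).
#' @param query_synonym_rate Probability a (non-Korean) query uses an
#'   English synonym instead of the representative term.
#' @param doc_relevance_rate Fraction of documents on-topic per concept.
#' @param vocabulary_size Background vocabulary size (Zipf-distributed).
#' @return List of class `cds_sim_config`.
#' @export
sim_config <- function(seed = 1L, n_concepts = 30L, synonyms_per_concept = 3L,
                       n_passages = 2000L, n_documents = 5000L,
                       sentences_range = c(2L, 4L), tokens_per_sentence = 7L,
                       relevance_rate = 0.01, abnormal_fraction = 0.5,
                       abnormal_passage_fraction = 0.4,
                       latent_cooccurrence_rate = 0.8,
                       latent_cooccurrence_rate_normal = 0.05,
                       latent_only_fraction = 0.3,
                       negation_trigger_rate = 1.0,
                       synonym_mention_rate = 0.3,
                       query_korean_rate = 0.25,
                       query_synonym_rate = 0.4,
                       doc_relevance_rate = 0.006,
                       vocabulary_size = 500L) {
  rates <- c(relevance_rate, abnormal_fraction, abnormal_passage_fraction,
             latent_cooccurrence_rate, latent_cooccurrence_rate_normal,
             latent_only_fraction,
             negation_trigger_rate, synonym_mention_rate, query_korean_rate,
             query_synonym_rate, doc_relevance_rate)
  stopifnot(all(rates >= 0), all(rates <= 1), n_concepts >= 1,
            n_passages >= 1, n_documents >= 1, vocabulary_size >= 1,
            seed == as.integer(seed))
  out <- as.list(environment())
  out$rates <- NULL
  for (f in c("seed", "n_concepts", "synonyms_per_concept", "n_passages",
              "n_documents", "tokens_per_sentence", "vocabulary_size"))
    out[[f]] <- as.integer(out[[f]])
  out$sentences_range <- as.integer(sentences_range)
  structure(out, class = "cds_sim_config")
}

# deterministic pseudo-word pool; avoids trigger/template English words
.sim_reserved <- c("no", "not", "normal", "negative", "increased", "high",
                   "elevated", "reduced", "detected", "test", "result",
                   "patients", "often", "require", "further", "testing",
                   "pattern", "associated", "considered", "should",
                   "concentration", "range", "levels", "stable", "remains",
                   "presenting", "laboratory", "frequently", "always",
                   "clinical", "setting", "management", "reviewed",
                   "section", "supports", "evaluation", "within", "unusual",
                   "most", "carefully", "careful", "extensively", "more",
                   "presence")

make_words <- function(n, min_syl = 2L, max_syl = 3L) {
  cons <- c("b", "d", "f", "g", "h", "k", "l", "m", "n", "p", "r", "s",
            "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  out <- character(0)
  while (length(out) < n) {
    batch <- vapply(seq_len(2L * (n - length(out)) + 10L), function(i) {
      ns <- sample(min_syl:max_syl, 1)
      paste0(paste0(sample(cons, ns, replace = TRUE),
                    sample(vow, ns, replace = TRUE), collapse = ""),
             sample(c("", cons), 1))
    }, character(1))
    out <- unique(c(out, setdiff(batch, .sim_reserved)))
  }
  out[seq_len(n)]
}

#' Generate a fixture ontology
#'
#' `n_concepts` Test instances, each with a representative English term, an
#' abbreviation, an English variant and one surrogate "Korean" surface
#' (ASCII `kx` prefix, matched verbatim as non-Latin surfaces are), plus a
#' linked Disease instance (the latent associate term), and Specimen and
#' Category instances wired through typed properties.
#'
#' @param config A [sim_config()].
#' @return A validated `cds_ontology`.
#' @export
make_fixture_ontology <- function(config = sim_config()) {
  set.seed(config$seed)
  nc <- config$n_concepts
  nsyn <- config$synonyms_per_concept
  words <- make_words(nc * (nsyn + 2L) + 20L)
  reps <- words[seq_len(nc)]
  dis <- words[nc + seq_len(nc)]
  rest <- words[-seq_len(2L * nc)]
  specimens <- c("serum", "urine", "blood", "plasma")
  categories <- c("hematology", "chemistry", "immunology", "microbiology")
  insts <- list()
  props <- list()
  for (i in seq_len(nc)) {
    syns <- character(0)
    if (nsyn >= 1) {  # abbreviation-style synonym
      ab <- substr(reps[i], 1, 3)
      syns <- c(syns, paste0(ab, i))
    }
    if (nsyn >= 3) {  # plain English variants
      extra <- rest[((i - 1L) * (nsyn - 2L) + 1L):((i - 1L) * (nsyn - 2L) +
                                                     (nsyn - 2L))]
      syns <- c(syns, extra)
    }
    if (nsyn >= 2) syns <- c(syns, paste0("kx", reps[i]))  # surrogate Korean
    tid <- sprintf("T%03d", i)
    did <- sprintf("D%03d", i)
    insts[[length(insts) + 1L]] <- list(
      id = tid, class = "Test", representative = reps[i],
      synonyms = syns,
      external_ids = list(umls = sprintf("C%07d", i)))
    insts[[length(insts) + 1L]] <- list(
      id = did, class = "Disease", representative = dis[i],
      synonyms = paste0("kx", dis[i]))
    props[[length(props) + 1L]] <- list(type = "test_disease", from = tid,
                                        to = did)
    props[[length(props) + 1L]] <- list(
      type = "test_specimen", from = tid,
      to = sprintf("S%03d", (i - 1L) %% length(specimens) + 1L))
    props[[length(props) + 1L]] <- list(
      type = "test_category", from = tid,
      to = sprintf("C%03d", (i - 1L) %% length(categories) + 1L))
  }
  for (j in seq_along(specimens))
    insts[[length(insts) + 1L]] <- list(id = sprintf("S%03d", j),
                                        class = "Specimen",
                                        representative = specimens[j],
                                        synonyms = character(0))
  for (j in seq_along(categories))
    insts[[length(insts) + 1L]] <- list(id = sprintf("C%03d", j),
                                        class = "Category",
                                        representative = categories[j],
                                        synonyms = character(0))
  propdf <- data.frame(
    type = vapply(props, `[[`, "", "type"),
    from = vapply(props, `[[`, "", "from"),
    to = vapply(props, `[[`, "", "to"), stringsAsFactors = FALSE)
  cds_ontology(insts, propdf)
}

# helpers shared by the corpus and query generators -------------------------

sim_concepts <- function(ontology) {
  tests <- Filter(function(i) i$class == "Test", ontology$instances)
  pr <- ontology$properties
  latent <- vapply(tests, function(t) {
    d <- pr$to[pr$type == "test_disease" & pr$from == t$id][1]
    ontology$instances[[d]]$representative
  }, character(1), USE.NAMES = FALSE)
  list(ids = unname(vapply(tests, `[[`, "", "id")),
       reps = unname(vapply(tests, `[[`, "", "representative")),
       synonyms = unname(lapply(tests, function(t) t$synonyms)),
       latent = latent)
}

cap1 <- function(s) paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))

sim_background_sentence <- function(vocab, zipf_p, len) {
  w <- sample(vocab, len, replace = TRUE, prob = zipf_p)
  paste0(cap1(paste(w, collapse = " ")), ".")
}

sim_concept_sentence <- function(surface, phrasing, trigger_rate) {
  # template pairs are balanced in content-token count (2,2,3,3 after
  # stopword removal) so neither phrasing is privileged by length
  # normalization in the scorers
  if (phrasing == "abnormal") {
    tpl <- sample(c("%s has been increased.", "%s is high.",
                    "The %s concentration has increased.",
                    "%s levels are elevated."), 1)
  } else if (stats::runif(1) <= trigger_rate) {
    tpl <- sample(c("%s is normal.", "No %s.", "%s result is negative.",
                    "%s is in the normal range."), 1)
  } else {
    tpl <- "%s remains stable."
  }
  sprintf(tpl, cap1(surface))
}

# length-matched to the background sentences so that no phrasing class is
# privileged by the length normalization of the scorers
sim_latent_sentence <- function(disease) {
  tpl <- sample(c("Patients presenting with %s often require further testing.",
                  "This unusual laboratory pattern is most frequently associated with %s.",
                  "%s should always be considered carefully in this clinical setting."),
                1)
  sprintf(tpl, disease)
}

#' Simulate passage and document corpora
#'
#' Plants, for every Test concept, a set of on-topic passages (abnormal- or
#' normal-phrased, sometimes referring to the concept by a synonym, often
#' co-mentioning the linked disease), a smaller set of disease-only
#' passages, and relevant documents in the global corpus where the test and
#' its disease co-occur; everything else is Zipf-distributed background.
#' All passages have at least two sentences. Bookkeeping of what was
#' planted where is returned for qrels construction.
#'
#' @param ontology Ontology from [make_fixture_ontology()].
#' @param config A [sim_config()].
#' @return List `passages` (data.frame), `documents` (data.frame), `meta`
#'   (per-concept planted ids and phrasings).
#' @export
simulate_corpus <- function(ontology, config = sim_config()) {
  set.seed(config$seed + 1L)
  con <- sim_concepts(ontology)
  nc <- length(con$ids)
  vocab <- setdiff(make_words(config$vocabulary_size + 200L),
                   c(ls(ontology$lexicon), .sim_reserved))[
                     seq_len(config$vocabulary_size)]
  zipf_p <- (1 / seq_along(vocab)); zipf_p <- zipf_p / sum(zipf_p)
  srange <- config$sentences_range
  bg_passage <- function(nsent = sample(srange[1]:srange[2], 1)) {
    paste(replicate(nsent, sim_background_sentence(
      vocab, zipf_p, config$tokens_per_sentence)), collapse = " ")
  }
  n_topic <- as.integer(round(config$relevance_rate * config$n_passages))
  n_latent <- round(config$latent_only_fraction * n_topic)
  texts <- character(0); owner <- character(0); kind <- character(0)
  for (i in seq_len(nc)) {
    n_abn <- round(config$abnormal_passage_fraction * n_topic)
    phr <- c(rep("abnormal", n_abn), rep("normal", n_topic - n_abn))
    for (ph in phr) {
      eng_syn <- setdiff(con$synonyms[[i]],
                         grep("^kx", con$synonyms[[i]], value = TRUE))
      surface <- if (length(eng_syn) &&
                     stats::runif(1) <= config$synonym_mention_rate)
        sample(eng_syn, 1) else con$reps[i]
      sents <- sim_concept_sentence(surface, ph,
                                    config$negation_trigger_rate)
      lat_rate <- if (ph == "abnormal") config$latent_cooccurrence_rate
                  else config$latent_cooccurrence_rate_normal
      if (stats::runif(1) <= lat_rate)
        sents <- c(sents, sim_latent_sentence(con$latent[i]))
      nbg <- max(2L - length(sents),
                 sample(srange[1]:srange[2], 1) - length(sents))
      if (nbg > 0)
        sents <- c(sents, replicate(nbg, sim_background_sentence(
          vocab, zipf_p, config$tokens_per_sentence)))
      texts <- c(texts, paste(sents, collapse = " "))
      owner <- c(owner, con$ids[i]); kind <- c(kind, ph)
    }
    for (j in seq_len(n_latent)) {
      # a disease-discussion passage names the disease in both sentences
      sents <- c(sim_latent_sentence(con$latent[i]),
                 sprintf("Careful management of %s is reviewed more extensively in this section.",
                         con$latent[i]))
      texts <- c(texts, paste(sents, collapse = " "))
      owner <- c(owner, con$ids[i]); kind <- c(kind, "latent")
    }
  }
  n_bg <- max(0L, config$n_passages - length(texts))
  texts <- c(texts, replicate(n_bg, bg_passage()))
  owner <- c(owner, rep(NA_character_, n_bg))
  kind <- c(kind, rep("background", n_bg))
  perm <- sample.int(length(texts))
  texts <- texts[perm]; owner <- owner[perm]; kind <- kind[perm]
  pids <- sprintf("P%05d", seq_along(texts))
  passages <- data.frame(
    passage_id = pids,
    source_id = sprintf("book%d", (seq_along(texts) - 1L) %% 3L + 1L),
    position = seq_along(texts), text = texts,
    sentence_count = vapply(texts, function(t) length(split_sentences(t)),
                            integer(1), USE.NAMES = FALSE),
    links = "", stringsAsFactors = FALSE)
  meta_p <- lapply(seq_len(nc), function(i) {
    sel <- !is.na(owner) & owner == con$ids[i]
    list(concept_id = con$ids[i],
         topic_ids = pids[sel & kind != "latent"],
         abnormal_ids = pids[sel & kind == "abnormal"],
         normal_ids = pids[sel & kind == "normal"],
         latent_only_ids = pids[sel & kind == "latent"])
  })
  names(meta_p) <- con$ids

  # global document corpus
  n_rel_doc <- as.integer(round(config$doc_relevance_rate * config$n_documents))
  dtexts <- character(0); downer <- character(0)
  for (i in seq_len(nc)) {
    for (j in seq_len(n_rel_doc)) {
      sents <- sprintf("The %s test supports this evaluation.", con$reps[i])
      if (stats::runif(1) <= config$latent_cooccurrence_rate)
        sents <- c(sents, sim_latent_sentence(con$latent[i]))
      nbg <- sample(2:4, 1)
      sents <- c(sents, replicate(nbg, sim_background_sentence(
        vocab, zipf_p, config$tokens_per_sentence)))
      dtexts <- c(dtexts, paste(sents, collapse = " "))
      downer <- c(downer, con$ids[i])
    }
  }
  n_bg_doc <- max(0L, config$n_documents - length(dtexts))
  dtexts <- c(dtexts, replicate(n_bg_doc, bg_passage(sample(3:6, 1))))
  downer <- c(downer, rep(NA_character_, n_bg_doc))
  dperm <- sample.int(length(dtexts))
  dtexts <- dtexts[dperm]; downer <- downer[dperm]
  dids <- sprintf("D%05d", seq_along(dtexts))
  documents <- data.frame(
    passage_id = dids, source_id = "webdocs", position = seq_along(dtexts),
    text = dtexts,
    sentence_count = vapply(dtexts, function(t) length(split_sentences(t)),
                            integer(1), USE.NAMES = FALSE),
    links = "", stringsAsFactors = FALSE)
  meta_d <- lapply(seq_len(nc), function(i)
    dids[!is.na(downer) & downer == con$ids[i]])
  names(meta_d) <- con$ids
  list(passages = passages, documents = documents,
       meta = list(passages = meta_p, documents = meta_d,
                   concepts = con))
}

#' Simulate queries and graded judgments
#'
#' One query per Test concept, split between normal and abnormal phrasings
#' per `abnormal_fraction`. Query surfaces exercise the translation path: a
#' fraction use the surrogate Korean surface, a further fraction an English
#' synonym. Judgments encode the clinical reading of the two intents: a
#' normal-result query is answered by reference-range (normal-phrased)
#' passages (definitely relevant) and, more weakly, abnormal-phrased ones
#' (possibly relevant); an abnormal-result query is answered by
#' abnormal-finding passages (definitely relevant) and disease-discussion
#' (latent-only) passages (possibly relevant), while normal-phrased
#' passages do not help it.
#'
#' @param ontology Ontology from [make_fixture_ontology()].
#' @param meta Bookkeeping from [simulate_corpus()].
#' @param config A [sim_config()].
#' @return List `queries` (data.frame `query_id`, `text`, `type`,
#'   `concept_id`) and `qrels` (a `cds_qrels`).
#' @export
simulate_queries_qrels <- function(ontology, meta, config = sim_config()) {
  set.seed(config$seed + 2L)
  con <- meta$concepts
  nc <- length(con$ids)
  n_abn <- round(config$abnormal_fraction * nc)
  types <- rep("normal", nc)
  types[sample.int(nc, n_abn)] <- "abnormal"
  qid <- sprintf("q%02d", seq_len(nc))
  texts <- character(nc)
  for (i in seq_len(nc)) {
    syns <- con$synonyms[[i]]
    kor <- grep("^kx", syns, value = TRUE)
    eng <- setdiff(syns, kor)
    u <- stats::runif(1)
    surface <- if (length(kor) && u <= config$query_korean_rate) {
      kor[1]
    } else if (length(eng) &&
               u <= config$query_korean_rate + config$query_synonym_rate) {
      sample(eng, 1)
    } else con$reps[i]
    texts[i] <- if (types[i] == "abnormal") {
      sprintf(sample(c("%s has been increased.",
                       "The %s concentration has increased.",
                       "%s is high."), 1), cap1(surface))
    } else {
      sprintf(sample(c("%s is normal.", "No %s.",
                       "%s test result is negative."), 1), cap1(surface))
    }
  }
  qq <- list(query_id = character(0), passage_id = character(0),
             grade = integer(0))
  addq <- function(qq, q, ids, g) {
    if (!length(ids)) return(qq)
    list(query_id = c(qq$query_id, rep(q, length(ids))),
         passage_id = c(qq$passage_id, ids),
         grade = c(qq$grade, rep(g, length(ids))))
  }
  for (i in seq_len(nc)) {
    mp <- meta$passages[[con$ids[i]]]
    if (types[i] == "normal") {
      qq <- addq(qq, qid[i], mp$normal_ids, 2L)
      qq <- addq(qq, qid[i], mp$abnormal_ids, 1L)
    } else {
      qq <- addq(qq, qid[i], mp$abnormal_ids, 2L)
      qq <- addq(qq, qid[i], mp$latent_only_ids, 1L)
    }
  }
  list(queries = data.frame(query_id = qid, text = texts, type = types,
                            concept_id = con$ids, stringsAsFactors = FALSE),
       qrels = qrels(qq$query_id, qq$passage_id, qq$grade))
}

#' Simulate a complete collection
#'
#' Convenience wrapper running [make_fixture_ontology()],
#' [simulate_corpus()] and [simulate_queries_qrels()] off one config.
#'
#' @param config A [sim_config()].
#' @return List `ontology`, `passages`, `documents`, `queries`, `qrels`,
#'   `meta`.
#' @export
simulate_collection <- function(config = sim_config()) {
  onto <- make_fixture_ontology(config)
  corp <- simulate_corpus(onto, config)
  qq <- simulate_queries_qrels(onto, corp$meta, config)
  list(ontology = onto, passages = corp$passages,
       documents = corp$documents, queries = qq$queries, qrels = qq$qrels,
       meta = corp$meta)
}
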