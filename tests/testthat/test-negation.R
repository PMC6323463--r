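# the six reference report sentences with their expected negation status
table3_cases <- function() {
  data.frame(
    text = c("AFP is normal", "No anemia", "HIV test is negative",
             "Eosinophil has been increased",
             "The uric acid concentration has increased",
             "Bilirubin is high"),
    concept = c("afp", "anemia", "hiv test", "eosinophil", "uric acid",
                "bilirubin"),
    status = c("negated", "negated", "negated", "affirmed", "affirmed",
               "affirmed"),
    stringsAsFactors = FALSE)
}

test_that("the default lexicon reproduces all six reference sentences", {
  onto <- fixture_ontology()
  lex <- negation_lexicon()
  cases <- table3_cases()
  for (k in seq_len(nrow(cases))) {
    ts <- tokenize_sentences(cases$text[k])
    m <- detect_and_translate(ts$tokens, onto)
    m <- detect_polarity(ts$tokens, m, lex, sentence = ts$sentence)
    hit <- m[m$representative == cases$concept[k], ]
    expect_identical(nrow(hit), 1L, info = cases$text[k])
    expect_identical(hit$polarity, cases$status[k], info = cases$text[k])
  }
})

test_that("the packaged lexicon file loads to the default triggers", {
  lex <- load_negation_lexicon(system.file("extdata",
                                           "negation_lexicon.json",
                                           package = "cdsearch"))
  expect_setequal(lex$pre_triggers, c("no", "not", "negative", "normal"))
  expect_setequal(lex$post_triggers, c("negative", "normal"))
  expect_identical(lex$window, 5L)
})

test_that("polarity never crosses sentence boundaries", {
  onto <- fixture_ontology()
  lex <- negation_lexicon()
  # trigger in the previous sentence must not negate the next concept
  ts <- tokenize_sentences("The result was normal. Eosinophil was measured.")
  m <- detect_polarity(ts$tokens, detect_and_translate(ts$tokens, onto),
                       lex, sentence = ts$sentence)
  expect_identical(m$polarity[m$representative == "eosinophil"], "affirmed")
  # same tokens in one sentence WOULD be negated (window covers it)
  flat <- detect_polarity(ts$tokens, detect_and_translate(ts$tokens, onto),
                          lex, sentence = NULL)
  expect_identical(flat$polarity[flat$representative == "eosinophil"],
                   "negated")
  # property over concatenations: each sentence keeps its own status
  cases <- table3_cases()
  set.seed(11)
  for (rep in 1:10) {
    pick <- sample(nrow(cases), 3)
    text <- paste0(cases$text[pick], ".", collapse = " ")
    ts <- tokenize_sentences(text)
    m <- detect_polarity(ts$tokens, detect_and_translate(ts$tokens, onto),
                         lex, sentence = ts$sentence)
    for (j in seq_along(pick)) {
      got <- m$polarity[m$representative == cases$concept[pick[j]]]
      expect_identical(got, cases$status[pick[j]],
                       info = paste(text, "->", cases$concept[pick[j]]))
    }
  }
})

test_that("window limits trigger reach", {
  onto <- fixture_ontology()
  toks <- tokenize("afp w1 w2 w3 w4 w5 w6 is maybe normal")
  m <- detect_and_translate(toks, onto)
  # "normal" is 9 tokens after the span: outside the default window of 5
  m5 <- detect_polarity(toks, m, negation_lexicon(window = 5))
  expect_identical(m5$polarity, "affirmed")
  m9 <- detect_polarity(toks, m, negation_lexicon(window = 9))
  expect_identical(m9$polarity, "negated")
})

test_that("out-of-range spans are reported", {
  m <- data.frame(instance_id = "T002", surface = "afp",
                  representative = "afp", start = 5L, end = 6L,
                  polarity = "unassessed", stringsAsFactors = FALSE)
  expect_error(detect_polarity(c("afp", "is", "normal"), m), "span")
})

test_that("apply_no_prefix rewrites only negated concepts' synonyms", {
  onto <- fixture_ontology()
  ts <- tokenize_sentences("AFP is normal. Bilirubin is high.")
  m <- detect_and_translate(ts$tokens, onto)
  q <- expand_synonyms(m, ontology_synonym_provider(onto), 0.5)
  m <- detect_polarity(ts$tokens, m, negation_lexicon(),
                       sentence = ts$sentence)
  out <- apply_no_prefix(q, m)
  # the negated concept's synonyms gain the prefix at unchanged weight
  expect_true("no-alpha-fetoprotein" %in% out$term)
  expect_identical(out$weight[out$term == "no-alpha-fetoprotein"], 0.5)
  # the affirmed concept's synonyms do not
  expect_true("tbil" %in% out$term)
  # original terms are never touched
  expect_true(all(c("afp", "bilirubin") %in%
                    out$term[out$origin == "original"]))
  expect_false(any(startsWith(out$term[out$origin == "original"], "no-")))
  # idempotent
  expect_identical(apply_no_prefix(out, m), out)
})

test_that("apply_no_prefix is a no-op without negation or synonyms", {
  onto <- fixture_ontology()
  ts <- tokenize_sentences("Bilirubin is high.")
  m <- detect_and_translate(ts$tokens, onto)
  m <- detect_polarity(ts$tokens, m, negation_lexicon(),
                       sentence = ts$sentence)
  q <- expand_synonyms(m, ontology_synonym_provider(onto), 0.5)
  expect_identical(apply_no_prefix(q, m), q)
  q2 <- weighted_query(c("afp", "gout"))
  expect_identical(apply_no_prefix(q2, m), q2)
})

test_that("query abnormality implements the inclusive inequality", {
  mk <- function(pol) data.frame(polarity = pol, stringsAsFactors = FALSE)
  expect_identical(query_abnormality(mk(c("negated")))$abn, 0L)
  expect_identical(query_abnormality(mk(c("affirmed")))$abn, 1L)
  expect_identical(query_abnormality(
    mk(c("affirmed", "affirmed", "negated", "negated")))$abn, 1L)
  # zero concepts: 0 >= 0 -> abnormal, the documented literal reading
  expect_identical(query_abnormality(mk(character(0)))$abn, 1L)
})

test_that("passage polarity counts tally per mention", {
  onto <- fixture_ontology()
  p <- passage_polarity_counts(
    "Eosinophil has been increased. Bilirubin is high.", onto)
  expect_identical(p$affirmed, 2L)
  expect_identical(p$negated, 0L)
  p2 <- passage_polarity_counts("HIV test is negative.", onto)
  expect_identical(p2$affirmed, 0L)
  expect_identical(p2$negated, 1L)
  p3 <- passage_polarity_counts("Nothing relevant here at all.", onto)
  expect_identical(p3$affirmed, 0L)
  expect_identical(p3$negated, 0L)
  # repeated mentions count once per mention
  p4 <- passage_polarity_counts("AFP rose. AFP is normal.", onto)
  expect_identical(p4$affirmed + p4$negated, 2L)
})
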