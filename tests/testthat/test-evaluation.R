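test_that("metric worked examples", {
  expect_equal(precision_at_n(c("a", "b", "c", "d", "e"),
                              c("a", "c", "e"), 5), 0.6)
  expect_equal(precision_at_n(character(0), "a", 5), 0)
  expect_equal(r_precision(c("a", "x", "b", "y"), c("a", "b", "c", "d")),
               0.5)
  expect_equal(r_precision(c("a", "b"), c("a", "b")), 1.0)
  expect_warning(val <- r_precision(c("a"), character(0)))
  expect_true(is.na(val))
  # perfect two-relevant ranking
  expect_equal(ndcg_at_n(c("a", "b"), c("a", "b"), 2), 1.0)
  # [rel, non, rel] with 2 relevant at n = 3
  expect_equal(ndcg_at_n(c("a", "x", "b"), c("a", "b"), 3),
               (1 + 1 / log2(3)) / (1 + 1 / log2(2)), tolerance = 1e-9)
  expect_equal(ndcg_at_n(c("x", "y"), c("a"), 5), 0)
  expect_equal(reciprocal_rank(c("x", "a"), "a"), 0.5)
  expect_equal(reciprocal_rank(c("x", "y"), "a"), 0)
})

test_that("mrr averages reciprocal ranks with zero for misses", {
  run <- data.frame(query_id = c("q1", "q1", "q2", "q2"),
                    passage_id = c("a", "b", "c", "d"),
                    rank = c(1L, 2L, 1L, 2L), score = c(2, 1, 2, 1),
                    tag = "t", stringsAsFactors = FALSE)
  qr <- qrels(c("q1", "q2"), c("a", "d"), c(2L, 1L))
  expect_equal(mrr(run, qr), mean(c(1, 0.5)))
  qr2 <- qrels("q1", "a", 2L)
  expect_equal(mrr(run, qr2), mean(c(1, 0)))
})

test_that("metrics agree with brute-force oracles on random instances", {
  set.seed(123)
  for (rep in 1:200) {
    npass <- sample(5:50, 1)
    ids <- sprintf("p%02d", seq_len(npass))
    ranked <- sample(ids, sample(3:npass, 1))
    relevant <- sample(ids, sample(seq_len(min(8, npass)), 1))
    n <- sample(1:10, 1)
    expect_equal(precision_at_n(ranked, relevant, n),
                 oracle_p_at_n(ranked, relevant, n), tolerance = 1e-12)
    expect_equal(r_precision(ranked, relevant),
                 oracle_rprec(ranked, relevant), tolerance = 1e-12)
    expect_equal(ndcg_at_n(ranked, relevant, n),
                 oracle_ndcg(ranked, relevant, n), tolerance = 1e-12)
    expect_equal(reciprocal_rank(ranked, relevant),
                 oracle_rr(ranked, relevant), tolerance = 1e-12)
  }
})

test_that("rank monotonicity: promoting a relevant passage never hurts", {
  set.seed(31)
  for (rep in 1:25) {
    ids <- sprintf("p%02d", 1:20)
    ranked <- sample(ids)
    relevant <- sample(ids, 5)
    pos <- which(ranked %in% relevant)
    pos <- pos[pos > 1][1]
    if (is.na(pos)) next
    swapped <- ranked
    swapped[c(pos - 1, pos)] <- swapped[c(pos, pos - 1)]
    for (n in c(5, 10, 20)) {
      expect_gte(ndcg_at_n(swapped, relevant, n),
                 ndcg_at_n(ranked, relevant, n))
    }
    expect_gte(reciprocal_rank(swapped, relevant),
               reciprocal_rank(ranked, relevant))
  }
})

test_that("permuting the irrelevant tail leaves P@n unchanged", {
  set.seed(17)
  ids <- sprintf("p%02d", 1:30)
  relevant <- ids[1:4]
  ranked <- c(ids[1:10], sample(ids[11:30]))
  ranked2 <- c(ids[1:10], sample(ids[11:30]))
  for (n in c(1, 5, 10))
    expect_equal(precision_at_n(ranked, relevant, n),
                 precision_at_n(ranked2, relevant, n))
})

test_that("qrels and run files round-trip in TREC format", {
  qr <- qrels(c("q1", "q1", "q2"), c("a", "b", "c"), c(2L, 1L, 0L))
  tq <- withr::local_tempfile(fileext = ".txt")
  write_qrels(qr, tq)
  expect_identical(read_qrels(tq), qr)
  run <- data.frame(query_id = "q1", passage_id = c("a", "b"), rank = 1:2,
                    score = c(0.9, 0.5), tag = "sys",
                    stringsAsFactors = FALSE)
  tr <- withr::local_tempfile(fileext = ".txt")
  write_run(run, tr)
  back <- read_run(tr)
  expect_identical(back$passage_id, run$passage_id)
  expect_identical(back$rank, run$rank)
  expect_equal(back$score, run$score, tolerance = 1e-6)
})

test_that("paired comparison handles identical, shifted and noisy runs", {
  set.seed(77)
  nq <- 12
  qids <- sprintf("q%02d", 1:nq)
  mkrun <- function(first_rel_at) {
    do.call(rbind, lapply(seq_len(nq), function(i) {
      ids <- c(sprintf("x%02d", 1:10))
      ids[first_rel_at[i]] <- "rel"
      data.frame(query_id = qids[i], passage_id = ids, rank = 1:10,
                 score = 10:1, tag = "t", stringsAsFactors = FALSE)
    }))
  }
  qr <- qrels(qids, rep("rel", nq), rep(2L, nq))
  a <- mkrun(rep(1L, nq))
  expect_identical(paired_comparison(a, a, qr, "RR")$p_value, 1)
  expect_identical(paired_comparison(a, a, qr, "RR")$mean_diff, 0)
  # constant shift: degenerate t, p -> 0
  b <- mkrun(rep(2L, nq))
  pc <- paired_comparison(a, b, qr, "RR")
  expect_equal(pc$mean_diff, 0.5, tolerance = 1e-12)
  expect_identical(pc$p_value, 0)
  # known noisy effect: compare p with a direct t-test re-derivation
  ra <- pmin(1 + rpois(nq, 1), 9)
  rb <- pmin(ra + sample(0:2, nq, replace = TRUE), 10)
  pa <- mkrun(ra); pb <- mkrun(rb)
  pc2 <- paired_comparison(pa, pb, qr, "RR")
  d <- 1 / ra - 1 / rb
  tt <- stats::t.test(d)
  expect_equal(pc2$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(pc2$mean_diff, mean(d), tolerance = 1e-12)
  expect_error(paired_comparison(a[a$query_id == "q01", ],
                                 a[a$query_id == "q01", ], qr, "RR"),
               "2 queries")
})

test_that("evaluate_run reports per-query and mean metrics", {
  run <- data.frame(query_id = rep("q1", 3),
                    passage_id = c("a", "x", "b"), rank = 1:3,
                    score = 3:1, tag = "t", stringsAsFactors = FALSE)
  qr <- qrels(c("q1", "q1"), c("a", "b"), c(2L, 1L))
  ev <- evaluate_run(run, qr, metrics = c("P5", "Rprec", "nDCG10", "RR"))
  expect_equal(unname(ev$mean["P5"]), 2 / 5)
  expect_equal(unname(ev$mean["Rprec"]), 1 / 2)
  expect_equal(unname(ev$mean["RR"]), 1)
  expect_warning(evaluate_run(run, qrels("q9", "a", 1L)), "missing")
})
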