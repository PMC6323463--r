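# hand-arithmetic oracle for the feedback weight of one term
prf_oracle <- function(alpha, beta, k, in_q, tf, N, pf, C, df) {
  s_raw <- alpha * as.numeric(in_q) * (if (N > 0) tf / N else 0) +
    (beta / k) * pf * (if (df > 0) log10((C + 1) / df) else 0)
  list(s_raw = s_raw, s = log10(10 + s_raw))
}

test_that("feedback weights match the hand-arithmetic oracle", {
  # corpus of 4 units; feedback = top-1 "a b b"
  idx <- build_index(data.frame(passage_id = c("u1", "u2", "u3", "u4"),
                                text = c("a b b", "a c", "c d", "b d")),
                     stopwords = NULL)
  cfg <- prf_config(alpha = 2, beta = 0.75, k = 1)
  tab <- prf_term_weights(weighted_query("a"), "u1", idx, cfg)
  oa <- prf_oracle(2, 0.75, 1, TRUE, 1, 3, 1, 4, 2)
  ob <- prf_oracle(2, 0.75, 1, FALSE, 2, 3, 1, 4, 2)
  expect_equal(tab$s_raw[tab$term == "a"], oa$s_raw, tolerance = 1e-12)
  expect_equal(tab$s[tab$term == "a"], oa$s, tolerance = 1e-12)
  expect_equal(tab$s_raw[tab$term == "b"], ob$s_raw, tolerance = 1e-12)
  # with equal corpus support, only the query term earns the alpha part
  expect_gt(tab$s_raw[tab$term == "a"], tab$s_raw[tab$term == "b"])
})

test_that("degenerate cases anchor at S_l = 1", {
  idx <- hand_index()
  # empty feedback: only query terms, s_raw 0, s 1
  tab <- prf_term_weights(weighted_query("a"), character(0), idx)
  expect_identical(tab$term, "a")
  expect_identical(tab$s_raw, 0)
  expect_identical(tab$s, 1)
  # alpha = beta = 0 collapses every weight
  tab2 <- prf_term_weights(weighted_query("a"), c("u1", "u2"), idx,
                           prf_config(alpha = 0, beta = 0, k = 2))
  expect_true(all(tab2$s_raw == 0))
  expect_true(all(tab2$s == 1))
})

test_that("root set is query terms united with feedback terms", {
  idx <- hand_index()
  tab <- prf_term_weights(weighted_query(c("zzz", "a")), c("u1", "u2"), idx,
                          prf_config(k = 2))
  expect_setequal(tab$term, c("zzz", "a", "b", "c"))
  # zzz appears nowhere: raw weight 0
  expect_identical(tab$s_raw[tab$term == "zzz"], 0)
})

test_that("query-term advantage is exactly alpha * tf / N", {
  idx <- build_index(data.frame(passage_id = c("u1", "u2", "u3"),
                                text = c("a b a b", "c d", "c e")),
                     stopwords = NULL)
  cfg <- prf_config(alpha = 2, k = 1)
  # a and b have identical feedback statistics (tf = 2, pf = 1, df = 1)
  tab <- prf_term_weights(weighted_query("a"), "u1", idx, cfg)
  diff <- tab$s_raw[tab$term == "a"] - tab$s_raw[tab$term == "b"]
  expect_equal(diff, 2 * 2 / 4, tolerance = 1e-12)
})

test_that("monotonicity: raising tf never lowers s_raw", {
  cfg <- prf_config()
  base <- build_index(data.frame(passage_id = "u1", text = "a b c c"),
                      stopwords = NULL)
  more <- build_index(data.frame(passage_id = "u1", text = "a b c c c"),
                      stopwords = NULL)
  t1 <- prf_term_weights(weighted_query("c"), "u1", base,
                         prf_config(k = 1))
  t2 <- prf_term_weights(weighted_query("c"), "u1", more,
                         prf_config(k = 1))
  expect_gte(t2$s_raw[t2$term == "c"], t1$s_raw[t1$term == "c"])
})

test_that("fusion follows the lambda mixture and is total over the union", {
  la <- data.frame(term = c("x", "y"), tf = 0, pf = 0, in_query = FALSE,
                   ipf = 0, s_raw = 0, s = c(2, 1.5))
  gl <- data.frame(term = c("x", "z"), tf = 0, pf = 0, in_query = FALSE,
                   ipf = 0, s_raw = 0, s = c(1, 1.2))
  f <- fuse_prf(la, gl, prf_config(lam = 0.65))
  expect_setequal(f$term, c("x", "y", "z"))
  expect_equal(f$s_prf[f$term == "x"], 0.65 * 2 + 0.35 * 1,
               tolerance = 1e-12)
  # missing-side terms use the degenerate value 1
  expect_equal(f$s_prf[f$term == "y"], 0.65 * 1.5 + 0.35 * 1,
               tolerance = 1e-12)
  expect_equal(f$s_prf[f$term == "z"], 0.65 * 1 + 0.35 * 1.2,
               tolerance = 1e-12)
  # lam = 1 reduces to the local table
  f1 <- fuse_prf(la, gl, prf_config(lam = 1))
  expect_equal(f1$s_prf[match(c("x", "y"), f1$term)], la$s)
  # equal tables are a fixed point for any lambda
  fx <- fuse_prf(la, la, prf_config(lam = 0.3))
  expect_equal(fx$s_prf[match(la$term, fx$term)], la$s)
  # s_prf always between the two sides
  expect_true(all(f$s_prf >= pmin(f$s_local, f$s_global) - 1e-12 &
                    f$s_prf <= pmax(f$s_local, f$s_global) + 1e-12))
})

test_that("expand_query appends exactly the top-m new terms, max-normalized", {
  q <- weighted_query("q1")
  fused <- data.frame(term = c("q1", "t1", "t2", "t3", "t4", "t5"),
                      s_local = 1, s_global = 1,
                      s_prf = c(3, 1.5, 1.1, 1.4, 1.2, 1.3),
                      in_query = c(TRUE, rep(FALSE, 5)))
  out <- expand_query(q, fused, prf_config(m = 3))
  added <- out[out$origin == "prf", ]
  # brute-force: the 3 largest s_prf among non-query terms
  expect_setequal(added$term, c("t1", "t3", "t5"))
  expect_equal(added$weight[added$term == "t1"], 1, tolerance = 1e-12)
  expect_equal(added$weight[added$term == "t3"], 1.4 / 1.5,
               tolerance = 1e-12)
  # originals preserved verbatim
  expect_identical(out$term[out$origin == "original"], "q1")
  expect_identical(out$weight[out$origin == "original"], 1)
  # m = 0 and all-candidates-in-query are identities
  expect_identical(expand_query(q, fused, prf_config(m = 0)), q)
  expect_identical(expand_query(q, fused[1, ], prf_config(m = 5)), q)
})

test_that("ties in s_prf break by ascending term string", {
  q <- weighted_query("q1")
  fused <- data.frame(term = c("bb", "aa", "cc"), s_local = 1, s_global = 1,
                      s_prf = c(1.2, 1.2, 1.2), in_query = FALSE)
  out <- expand_query(q, fused, prf_config(m = 2))
  expect_identical(out$term[out$origin == "prf"], c("aa", "bb"))
})
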