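test_that("precision/recall/F arithmetic matches the reporting conventions", {
  # harmonic-mean identity: F from counts equals 2PR/(P+R) when defined
  set.seed(2)
  for (i in 1:50) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    v <- prf(eval_counts(tp, fp, fn), digits = NULL)
    if (v$precision + v$recall > 0)
      expect_equal(v$f, 2 * v$precision * v$recall / (v$precision + v$recall))
    else expect_identical(v$f, 0)
  }
  # empty convention
  expect_identical(prf(eval_counts(0, 0, 0)),
                   list(precision = 0, recall = 0, f = 0))
  # one-decimal half-up reporting
  expect_equal(prf(eval_counts(1, 2, 0))$precision, 33.3)
  expect_equal(prf(eval_counts(1, 3, 0))$precision, 25)
  expect_equal(prf(eval_counts(5, 3, 0))$precision, 62.5)
})

test_that("term-level scoring distinguishes namespaces unless orthologs allowed", {
  gold <- list(parse_bel("p(HGNC:IL12B)"))
  pred <- list(parse_bel("p(MGI:IL12b)"))
  sc <- score_sentence(gold, pred)
  t_row <- sc[sc$level == "T", ]
  expect_identical(t_row$fn, 1L)
  expect_identical(t_row$fp, 1L)
  expect_identical(t_row$tp, 0L)

  tol <- tolerance_config(ortholog_map = data.frame(
    ns_a = "HGNC", id_a = "IL12B", ns_b = "MGI", id_b = "IL12b",
    stringsAsFactors = FALSE))
  sc2 <- score_sentence(gold, pred, tol)
  t_row2 <- sc2[sc2$level == "T", ]
  expect_identical(t_row2$tp, 1L)
  expect_identical(t_row2$fp + t_row2$fn, 0L)
})

test_that("a missed activity function is a FN at Function and Secondary Function", {
  gold <- list(parse_bel("act(p(HGNC:STAT3))"))
  pred <- list(parse_bel("p(HGNC:STAT3)"))
  sc <- score_sentence(gold, pred)
  expect_identical(sc[sc$level == "F", ]$fn, 1L)
  expect_identical(sc[sc$level == "Fs", ]$fn, 1L)
  expect_identical(sc[sc$level == "F", ]$fp, 0L)
  # term level is unaffected by the wrapper
  expect_identical(sc[sc$level == "T", ]$tp, 1L)
  # function equivalence: act() accepted for kin()
  gold_kin <- list(parse_bel("kin(p(HGNC:STAT3))"))
  pred_act <- list(parse_bel("act(p(HGNC:STAT3))"))
  sc2 <- score_sentence(gold_kin, pred_act)
  expect_identical(sc2[sc2$level == "F", ]$tp, 1L)
})

test_that("relation levels grade partial matches correctly", {
  gold <- list(parse_bel("p(HGNC:A1) increases r(HGNC:B1)"))
  # wrong object, correct subject and relationship -> Rs TP, R FN
  pred <- list(parse_bel("p(HGNC:A1) increases r(HGNC:C1)"))
  sc <- score_sentence(gold, pred)
  expect_identical(sc[sc$level == "Rs", ]$tp, 1L)
  expect_identical(sc[sc$level == "R", ]$tp, 0L)
  # only the subject correct -> no Rs credit
  pred2 <- list(parse_bel("p(HGNC:A1) decreases r(HGNC:C1)"))
  sc2 <- score_sentence(gold, pred2)
  expect_identical(sc2[sc2$level == "Rs", ]$tp, 0L)
  # a deg() mismatch breaks S but not R (entity-level sides)
  gold3 <- list(parse_bel("p(HGNC:A1) increases deg(p(HGNC:B1))"))
  pred3 <- list(parse_bel("p(HGNC:A1) increases p(HGNC:B1)"))
  sc3 <- score_sentence(gold3, pred3)
  expect_identical(sc3[sc3$level == "R", ]$tp, 1L)
  expect_identical(sc3[sc3$level == "S", ]$tp, 0L)
})

test_that("self-scoring is perfect and swapping sides swaps FP and FN", {
  pool <- random_bel_statements(n = 40, seed = 13)
  set.seed(13)
  for (i in 1:25) {
    gold <- pool[sample(40, sample(0:5, 1))]
    pred <- pool[sample(40, sample(0:5, 1))]
    self <- score_sentence(gold, gold)
    expect_true(all(self$fp == 0) && all(self$fn == 0))
    ab <- score_sentence(gold, pred)
    ba <- score_sentence(pred, gold)
    expect_identical(ab$tp, ba$tp)
    expect_identical(ab$fp, ba$fn)
    expect_identical(ab$fn, ba$fp)
    # partial credit dominates: Rs >= R >= S true positives
    expect_gte(ab$tp[ab$level == "Rs"], ab$tp[ab$level == "R"])
    expect_gte(ab$tp[ab$level == "R"], ab$tp[ab$level == "S"])
  }
})

test_that("corpus scoring sums counts and validates sentence ids", {
  g <- list(S1 = list(parse_bel("p(HGNC:A1) increases r(HGNC:B1)"),
                      parse_bel("p(HGNC:C1)")),
            S2 = list(parse_bel("p(HGNC:A1) decreases r(HGNC:B1)")))
  p <- list(S1 = list(parse_bel("p(HGNC:A1) increases r(HGNC:B1)")),
            S2 = list(parse_bel("p(HGNC:A1) increases r(HGNC:B1)")))
  rep <- score_corpus(g, p)
  lv <- rep$levels
  # totals equal the per-sentence sums
  for (L in lv$level) {
    s1 <- rep$per_sentence[["S1"]]; s2 <- rep$per_sentence[["S2"]]
    expect_identical(lv[lv$level == L, ]$tp,
                     s1[s1$level == L, ]$tp + s2[s2$level == L, ]$tp)
  }
  # two sentences each scoring (1,1,1) give F = 50.0
  gg <- list(S1 = list(parse_bel("p(HGNC:A1)"), parse_bel("p(HGNC:B1)")),
             S2 = list(parse_bel("p(HGNC:A1)"), parse_bel("p(HGNC:B1)")))
  pp <- list(S1 = list(parse_bel("p(HGNC:A1)"), parse_bel("p(HGNC:X1)")),
             S2 = list(parse_bel("p(HGNC:A1)"), parse_bel("p(HGNC:X1)")))
  rep2 <- score_corpus(gg, pp)
  expect_equal(rep2$levels[rep2$levels$level == "T", ]$f, 50)
  # empty predictions: zero precision and recall, gold counted FN
  rep3 <- score_corpus(gg, list())
  expect_equal(rep3$levels[rep3$levels$level == "T", ]$precision, 0)
  expect_identical(rep3$levels[rep3$levels$level == "T", ]$fn, 4L)
  # missing-sentence prediction counts all gold as FN
  rep4 <- score_corpus(gg, pp[1])
  expect_identical(rep4$levels[rep4$levels$level == "T", ]$fn, 3L)
})

test_that("the matcher equals exhaustive optimal matching", {
  pool <- random_bel_statements(n = 25, seed = 21)
  feats <- lapply(pool, belminer:::.statement_features,
                  tol = tolerance_config())
  set.seed(21)
  for (i in 1:60) {
    gi <- sample(25, sample(0:5, 1)); pi <- sample(25, sample(0:5, 1))
    sc <- score_sentence(pool[gi], pool[pi])
    rsig <- function(f) paste(f$subj, f$rel, f$obj)
    # Rs level against brute force
    M <- matrix(FALSE, length(gi), length(pi))
    for (a in seq_along(gi)) for (b in seq_along(pi)) {
      fg <- feats[[gi[a]]]; fp <- feats[[pi[b]]]
      M[a, b] <- (fg$subj == fp$subj) + (fg$rel == fp$rel) +
        (fg$obj == fp$obj) >= 2
    }
    expect_identical(sc[sc$level == "Rs", ]$tp, oracle_max_match(M))
    # exact levels against brute force on equality matrices
    for (L in c("R", "S")) {
      sig <- switch(L, R = rsig, S = function(f) f$full)
      Me <- outer(vapply(feats[gi], sig, character(1)),
                  vapply(feats[pi], sig, character(1)), "==")
      expect_identical(sc[sc$level == L, ]$tp, oracle_max_match(Me))
    }
    # term items: multiset counting equals exhaustive matching
    g_items <- as.character(unlist(lapply(feats[gi], `[[`, "terms")))
    p_items <- as.character(unlist(lapply(feats[pi], `[[`, "terms")))
    Mt <- outer(g_items, p_items, "==")
    expect_identical(sc[sc$level == "T", ]$tp, oracle_max_match(Mt))
  }
})

test_that("paired t-test matches the textbook formula and stats::t.test", {
  a <- c(49.8, 52.5, 53.7, 51.7, 40.2)
  b <- c(33.7, 45.2, 44.6, 41.7, 39.9)
  res <- paired_ttest(a, b)
  d <- a - b
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(5)))
  expect_identical(res$df, 4L)
  expect_equal(res$t, unname(t.test(a, b, paired = TRUE)$statistic))
  # identical lists: t = 0, not significant
  same <- paired_ttest(a, a)
  expect_identical(same$t, 0)
  expect_false(same$significant)
  # zero variance with non-zero mean difference: infinite t, flagged
  zv <- paired_ttest(a + 1, a)
  expect_identical(zv$t, Inf)
  expect_true(zv$zero_variance)
  expect_true(zv$significant)
  # critical value at df = 29 is the printed 1.70 threshold
  x <- rnorm(30); y <- x + rnorm(30)
  expect_equal(paired_ttest(x, y)$critical, 1.7)
})

test_that("per-group F-scores partition sentences contiguously", {
  pool <- random_bel_statements(n = 10, seed = 31)
  gold <- setNames(lapply(1:12, function(i) pool[sample(10, 2)]),
                   sprintf("S%02d", 1:12))
  pred <- gold
  rep <- score_corpus(gold, pred)
  fs <- level_fscores(rep, "S", groups = 4)
  expect_length(fs, 4)
  expect_true(all(fs == 100))
  expect_error(level_fscores(rep, "S", groups = 30), "cannot split")
})
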