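test_that("pool_candidates unions spans and builds signatures", {
  a <- make_spans(0L); b <- make_spans(10L); c <- make_spans(20L)
  cands <- pool_candidates(list(e1 = rbind(a, b), e2 = rbind(a, c)))
  sig <- stats::setNames(cands$signature, cands$start)
  expect_equal(sig[["0"]], "11")
  expect_equal(sig[["10"]], "10")
  expect_equal(sig[["20"]], "01")
  expect_equal(attr(cands, "extractors"), c("e1", "e2"))

  same <- pool_candidates(list(x = rbind(a, b), y = rbind(a, b)))
  expect_true(all(same$signature == "11"))
  expect_equal(nrow(pool_candidates(list(only = a[0, ]))), 0L)
  expect_error(pool_candidates(list()), "at least one")
  expect_error(pool_candidates(list(a, b)), "named")
})

test_that("estimate_table computes derived-extractor precisions", {
  # gold = {a,b,c}; E1 = {a,b,d}; E2 = {a,d,e}
  gold <- make_spans(c(0L, 1L, 2L))
  e1 <- make_spans(c(0L, 1L, 3L))
  e2 <- make_spans(c(0L, 3L, 4L))
  tab <- estimate_table(list(e1 = e1, e2 = e2), gold)
  p <- stats::setNames(tab$cells$probability, tab$cells$signature)
  expect_equal(p[["11"]], 0.5)  # {a, d}, a is gold
  expect_equal(p[["10"]], 1.0)  # {b}
  expect_equal(p[["01"]], 0.0)  # {e}

  single <- estimate_table(list(only = gold), gold)
  expect_equal(single$cells$probability, 1.0)

  # empty gold is legal: every probability 0
  tab0 <- estimate_table(list(e1 = e1, e2 = e2), gold[0, ])
  expect_true(all(tab0$cells$probability[tab0$cells$candidates > 0] == 0))
  expect_error(estimate_table(list(e1 = e1[0, ]), gold), "empty candidate")
})

test_that("a three-extractor table exposes exactly 7 cells", {
  outs <- list(a = make_spans(0:3), b = make_spans(2:5), c = make_spans(4:8))
  tab <- estimate_table(outs, make_spans(c(0L, 2L, 4L)))
  expect_equal(nrow(tab$cells), 7L)
  expect_equal(sum(tab$cells$candidates), nrow(pool_candidates(outs)))
})

test_that("estimates match the brute-force set-algebra oracle", {
  set.seed(41)
  for (rep in 1:40) {
    inst <- random_ensemble_instance()
    tab <- estimate_table(inst$outputs, inst$gold)
    for (i in seq_len(nrow(tab$cells))) {
      oracle <- oracle_cell_precision(inst$outputs, inst$gold,
                                      tab$cells$signature[i])
      if (is.na(oracle)) {
        expect_true(is.na(tab$cells$probability[i]))
        expect_equal(tab$cells$candidates[i], 0L)
      } else {
        expect_equal(tab$cells$probability[i], oracle)
      }
    }
  }
})

test_that("scoring reproduces published-style confidences from a table file", {
  # a table over three taggers, stored as counts whose ratios equal the
  # published per-signature probabilities for the two quoted cells
  tf <- tempfile()
  writeLines(c(
    "tagger\toscar\tchemspot\tcandidates\thits\tprobability",
    "1\t0\t0\t100000\t25200\t0.252",
    "0\t1\t0\t100000\t8900\t0.089",
    "0\t0\t1\t100000\t24900\t0.249",
    "1\t1\t0\t100000\t82083\t0.82083",
    "1\t0\t1\t100000\t72799\t0.72799",
    "0\t1\t1\t100000\t55869\t0.55869",
    "1\t1\t1\t100000\t93316\t0.93316"), tf)
  tab <- read_conditional_table(tf)
  expect_equal(tab$extractors, c("tagger", "oscar", "chemspot"))

  spans <- make_spans(c(0L, 10L))
  cands <- data.frame(spans[1:2, ], signature = c("011", "111"))
  attr(cands, "extractors") <- tab$extractors
  scored <- score_candidates(cands, tab)
  expect_equal(scored$confidence, c(0.55869, 0.93316))

  # round trip through the TSV writer
  tf2 <- tempfile()
  write_conditional_table(tab, tf2)
  expect_equal(read_conditional_table(tf2)$cells, tab$cells)
})

test_that("missing-cell fallbacks behave per policy", {
  # disjoint extractors: the joint signature "11" is never realized
  gold <- make_spans(c(0L, 1L))
  e1 <- make_spans(c(0L, 5L))   # single-extractor precision 1/2
  e2 <- make_spans(c(1L, 9L))   # single-extractor precision 1/2
  tab <- estimate_table(list(e1 = e1, e2 = e2), gold)
  expect_true(is.na(tab$cells$probability[tab$cells$signature == "11"]))

  cands <- data.frame(make_spans(100L), signature = "11")
  attr(cands, "extractors") <- c("e1", "e2")
  expect_equal(score_candidates(cands, tab, fallback = "zero")$confidence, 0)
  expect_error(score_candidates(cands, tab, fallback = "error"),
               "no estimated")
  singles <- stats::setNames(tab$cells$probability, tab$cells$signature)
  expect_equal(score_candidates(cands, tab)$confidence,
               mean(c(singles[["10"]], singles[["01"]])))

  bad <- cands
  attr(bad, "extractors") <- c("e2", "e1")
  expect_error(score_candidates(bad, tab), "order mismatch")
})

test_that("thresholding and the PR curve behave monotonically", {
  set.seed(42)
  inst <- random_ensemble_instance(3L, 40L)
  tab <- estimate_table(inst$outputs, inst$gold)
  scored <- ensemble_score(inst$outputs, tab)

  expect_equal(nrow(apply_threshold(scored, 0)), nrow(scored))
  expect_equal(nrow(apply_threshold(scored, 1)),
               sum(scored$confidence == 1))
  expect_error(apply_threshold(scored, 1.5), "tau")

  curve <- pr_curve(scored, inst$gold)
  expect_true(!is.unsorted(curve$tau))
  expect_true(all(diff(curve$recall) <= 1e-12))
  expect_true(all(diff(curve$retained) <= 0))
  # recall at tau = 0 equals recall of the union of all extractors
  union_recall <- evaluate_cem(inst$gold, scored)$recall
  expect_equal(curve$recall[1], union_recall)
})

test_that("self-scoring precision never falls below the threshold", {
  set.seed(43)
  for (rep in 1:10) {
    inst <- random_ensemble_instance(3L, 60L)
    tab <- estimate_table(inst$outputs, inst$gold)
    scored <- ensemble_score(inst$outputs, tab)
    for (tau in unique(scored$confidence)) {
      kept <- apply_threshold(scored, tau)
      if (nrow(kept) > 0L) {
        expect_gte(evaluate_cem(inst$gold, kept)$precision, tau - 1e-12)
      }
    }
  }
})

test_that("pr_curve worked example: tau above the mixed cell keeps only pure hits", {
  gold <- make_spans(c(0L, 1L, 2L))
  e1 <- make_spans(c(0L, 1L, 3L))
  e2 <- make_spans(c(0L, 3L, 4L))
  tab <- estimate_table(list(e1 = e1, e2 = e2), gold)
  scored <- ensemble_score(list(e1 = e1, e2 = e2), tab)
  kept <- apply_threshold(scored, 0.6)   # only the P=1 cell {b} survives
  ev <- evaluate_cem(gold, kept)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1 / 3)
})
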