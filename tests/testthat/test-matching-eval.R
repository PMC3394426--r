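apair <- function(ab, ff, cid, chem = FALSE) {
  data.frame(abbreviation = ab, full_form = ff, concept_id = cid,
             is_chemical = chem, stringsAsFactors = FALSE)
}

test_that("candidate generation pairs A-pairs sharing an abbreviation", {
  ap <- rbind(apair("dgme", "diethylene glycol monoethyl ether", "c1", TRUE),
              apair("dgme", "diethylene glycol monomethyl ether", "c2", TRUE))
  cand <- generate_candidates(ap)
  expect_identical(nrow(cand), 1L)
  expect_false(cand$gold)
  expect_true(cand$is_chemical)

  ap3 <- rbind(apair("dgme", "form a", "c1"), apair("dgme", "form b", "c1"),
               apair("dgme", "form c", "c2"))
  expect_identical(nrow(generate_candidates(ap3)), 3L)  # C(3, 2)
  expect_identical(sum(generate_candidates(ap3)$gold), 1L)

  ap2 <- rbind(apair("aa", "form a", "c1"), apair("bb", "form b", "c1"))
  expect_identical(nrow(generate_candidates(ap2)), 0L)
  expect_identical(nrow(generate_candidates(ap2[0, ])), 0L)

  # deterministic order regardless of input order
  set.seed(1)
  big <- rbind(ap3, apair("zz", "x y", "c9"), apair("zz", "x z", "c9"))
  expect_identical(generate_candidates(big[sample(nrow(big)), ]),
                   generate_candidates(big))
})

test_that("score_pairs applies the chosen measure elementwise", {
  ap <- rbind(apair("ab", "alpha beta", "c1"), apair("ab", "alpha betta", "c1"),
              apair("ab", "gamma", "c2"), apair("ab", "alpha gamma", "c3"),
              apair("ab", "delta epsilon", "c4"))
  cand <- generate_candidates(ap)
  sc <- score_pairs(cand, "edit")
  expect_identical(sc$score,
                   normalized_edit_distance(cand$full_form_1,
                                            cand$full_form_2))
  expect_identical(attr(sc, "direction"), "distance")
  sc2 <- score_pairs(cand, "bigram_dice")
  expect_identical(sc2$score, ngram_dice(cand$full_form_1, cand$full_form_2))
  expect_identical(attr(sc2, "direction"), "similarity")
  # identical full forms: distance 0 / dice on disjoint strings 0
  ident <- generate_candidates(rbind(apair("q", "same form", "c1"),
                                     apair("q", "same form", "c1")))
  expect_identical(score_pairs(ident, "edit")$score, 0)
  disj <- generate_candidates(rbind(apair("q", "ab", "c1"),
                                    apair("q", "cd", "c2")))
  expect_identical(score_pairs(disj, "bigram_dice")$score, 0)
  expect_error(score_pairs(cand, "unknown"))
})

test_that("evaluate_at computes the confusion matrix with strict cutoffs", {
  # TP=2, FP=1, FN=2 at threshold 0.5
  p <- make_scored_pairs(c(0.1, 0.2, 0.3, 0.7, 0.9),
                         c(TRUE, TRUE, FALSE, TRUE, TRUE))
  pt <- evaluate_at(p, 0.5)
  expect_equal(pt$precision, 2 / 3)
  expect_equal(pt$recall, 1 / 2)
  expect_equal(pt$f_measure, 4 / 7)
  # strictness: a score equal to the threshold is not predicted
  expect_identical(evaluate_at(p, 0.1)$n_predicted, 0L)
  none <- evaluate_at(p, 0)
  expect_identical(c(none$precision, none$recall, none$f_measure), c(0, 0, 0))
  # similarity sense flips the inequality
  ps <- make_scored_pairs(c(0.9, 0.4), c(TRUE, FALSE), "similarity")
  expect_identical(evaluate_at(ps, 0.5)$n_predicted, 1L)
  expect_equal(evaluate_at(ps, 0.5)$precision, 1)
})

test_that("sweeps agree with pointwise evaluation and are monotone", {
  set.seed(41)
  p <- make_scored_pairs(round(runif(60), 2), runif(60) < 0.4)
  sw <- sweep_thresholds(p, grid = "coarse")
  expect_identical(sw$threshold, seq(0, 1, by = 0.05))
  for (k in c(1, 5, 11, 21)) {
    pt <- evaluate_at(p, sw$threshold[k])
    expect_equal(sw[k, ], pt, ignore_attr = TRUE)
  }
  expect_false(is.unsorted(sw$n_predicted))
  expect_false(is.unsorted(sw$recall))
  # similarity direction: loosening means lowering the threshold
  ps <- make_scored_pairs(round(runif(60), 2), runif(60) < 0.4, "similarity")
  sws <- sweep_thresholds(ps, grid = "observed")
  expect_false(is.unsorted(rev(sws$n_predicted)))
  expect_false(is.unsorted(rev(sws$recall)))
  # all-gold fixture: precision 1 wherever something is predicted
  pg <- make_scored_pairs(runif(20), rep(TRUE, 20))
  swg <- sweep_thresholds(pg, grid = "observed")
  expect_true(all(swg$precision[swg$n_predicted > 0] == 1))
  expect_identical(threshold_grid("fine"), seq(0.900, 0.995, by = 0.005))
})

test_that("best_threshold maximizes F with stricter-threshold tie-breaking", {
  sw <- data.frame(threshold = c(0.2, 0.4), precision = c(0.5, 0.5),
                   recall = c(0.5, 0.5), f_measure = c(0.5, 0.5),
                   n_predicted = c(2L, 3L))
  expect_identical(best_threshold(sw, "distance")$threshold, 0.2)
  expect_identical(best_threshold(sw, "similarity")$threshold, 0.4)
  expect_identical(best_threshold(sw[1, ], "distance"), sw[1, ])
  set.seed(43)
  p <- make_scored_pairs(round(runif(50), 2), runif(50) < 0.5)
  got <- best_f_point(p)
  want <- oracle_best_f(p$score, p$gold, "distance")
  expect_equal(unlist(got), want, tolerance = 1e-12)
})

test_that("PR curve equals the tie-grouped prefix scan", {
  # two-pair enumeration: one positive ranked first
  p2 <- make_scored_pairs(c(0.1, 0.2), c(TRUE, FALSE))
  pc2 <- pr_curve(p2)
  expect_equal(pc2$recall, c(1, 1))
  expect_equal(pc2$precision, c(1, 0.5))
  # all-gold: precision 1 along the whole curve
  pg <- make_scored_pairs(runif(15), rep(TRUE, 15))
  expect_true(all(pr_curve(pg)$precision == 1))
  expect_error(pr_curve(make_scored_pairs(runif(5), rep(FALSE, 5))),
               "gold-positive")
  set.seed(47)
  p <- make_scored_pairs(round(runif(100), 2), runif(100) < 0.3)
  got <- pr_curve(p)
  want <- oracle_pr_curve(p$score, p$gold, "distance")
  expect_equal(got$recall, unname(want[, "recall"]))
  expect_equal(got$precision, unname(want[, "precision"]))
  expect_equal(got$n_selected, unname(want[, "n_selected"]))
  # realized sweep points lie on the curve
  sw <- sweep_thresholds(p, grid = "observed")
  on_curve <- sw[sw$n_predicted > 0, ]
  for (k in seq_len(nrow(on_curve))) {
    row <- got[got$n_selected == on_curve$n_predicted[k], ]
    expect_identical(nrow(row), 1L)
    expect_equal(row$precision, on_curve$precision[k])
    expect_equal(row$recall, on_curve$recall[k])
  }
})

test_that("fixed-recall selection picks the prefix with the closest recall", {
  # recall 1 target covers all positives
  p <- make_scored_pairs(seq(0.1, 1, by = 0.1),
                         c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE,
                           TRUE, FALSE))
  full <- threshold_at_recall(p, 1)
  expect_equal(full$recall, 1)
  expect_identical(full$n_selected, 9L)
  # achievable recalls straddle 0.8: 6/8 = 0.75 wins over 7/8 = 0.875
  p8 <- make_scored_pairs(seq(0.1, 1, by = 0.1),
                          c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE,
                            TRUE, FALSE))
  sel <- threshold_at_recall(p8, 0.8)
  expect_equal(sel$recall, 0.75)
  expect_identical(sel$n_selected, 6L)
  expect_equal(sel$threshold, 0.6)
  set.seed(53)
  pr <- make_scored_pairs(round(runif(80), 2), runif(80) < 0.4)
  got <- threshold_at_recall(pr, 0.8)
  want <- oracle_threshold_at_recall(pr$score, pr$gold, "distance", 0.8)
  expect_equal(unlist(got), want, tolerance = 1e-12)
  expect_error(threshold_at_recall(make_scored_pairs(1, FALSE), 0.8),
               "gold-positive")
})

test_that("split-vs-mixed comparison pools per-subset selections correctly", {
  gold <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  scores <- seq(0.05, 0.5, by = 0.05)
  a <- make_scored_pairs(scores, gold)
  cmp_same <- compare_split_vs_mixed(a, a, target_recall = 0.8)
  expect_equal(cmp_same$precision[cmp_same$subset == "all"],
               cmp_same$precision[cmp_same$subset == "mixed"])
  # chemical positives separate at a stricter threshold: split beats mixed
  chem <- make_scored_pairs(c(0.02, 0.04, 0.06, 0.08, 0.10, 0.12, 0.14, 0.16),
                            c(TRUE, TRUE, TRUE, TRUE, TRUE,
                              FALSE, FALSE, FALSE))
  oth <- make_scored_pairs(c(0.11, 0.13, 0.30, 0.35, 0.40, 0.45, 0.50, 0.55),
                           c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE,
                             FALSE))
  cmp <- compare_split_vs_mixed(chem, oth, target_recall = 0.8)
  split_p <- cmp$precision[cmp$subset == "all"]
  mixed_p <- cmp$precision[cmp$subset == "mixed"]
  expect_gt(split_p, mixed_p)
  # per-subset rows equal direct fixed-recall selections
  expect_equal(cmp[cmp$subset == "chemical", -1],
               threshold_at_recall(chem, 0.8), ignore_attr = TRUE)
  expect_equal(cmp[cmp$subset == "other", -1],
               threshold_at_recall(oth, 0.8), ignore_attr = TRUE)
  # mixed row equals the pooled fixed-recall selection bit-for-bit
  pooled <- rbind(chem, oth)
  attr(pooled, "direction") <- "distance"
  expect_identical(unlist(cmp[cmp$subset == "mixed", -1], use.names = FALSE),
                   unlist(threshold_at_recall(pooled, 0.8),
                          use.names = FALSE))
  expect_error(compare_split_vs_mixed(chem, chem[0, ], 0.8, "distance"),
               "gold-positive")
  expect_error(compare_split_vs_mixed(
    make_scored_pairs(runif(4), rep(FALSE, 4)), oth, 0.8, "distance"),
    "gold-positive")
})
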