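# ROC/AUC, confusion metrics, precision/recall at k, fold enrichment,
# percentile retrieval.

test_that("perfect ranking gives AUC 1 and degenerate labels error", {
  tr <- make_trials(list(
    list(held_out = "A", candidates = c("A", "B", "C"), scores = c(3, 2, 1)),
    list(held_out = "D", candidates = c("D", "E"), scores = c(9, 1))
  ))
  expect_equal(roc_auc(tr)$auc, 1)
  expect_equal(tr$rank, c(1L, 1L))

  one_sided <- make_trials(list(
    list(held_out = "A", candidates = "A", scores = 1)))
  expect_error(roc_auc(one_sided), "positive and negative")
})

test_that("one discordant pair out of four gives AUC 0.75", {
  tr <- make_trials(list(
    list(held_out = "P1", candidates = c("P1", "P2"), scores = c(0.9, 0.1)),
    list(held_out = "P3", candidates = c("P3", "P4"), scores = c(0.3, 0.4))
  ))
  expect_equal(roc_auc(tr)$auc, 0.75)
})

test_that("threshold-sweep AUC equals the Mann-Whitney statistic", {
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(20:200, 1)
    score <- round(runif(n), sample(1:3, 1))  # force ties
    label <- runif(n) < 0.3
    if (!any(label) || all(label)) next
    sweep <- lpihn:::.sweep_roc(score, label)
    expect_equal(sweep$auc, mw_auc(score, label), tolerance = 1e-10)
  }
  # and against pROC on one fixed case
  skip_if_not_installed("pROC")
  set.seed(34)
  score <- runif(300)
  label <- runif(300) < 0.25
  expect_equal(
    lpihn:::.sweep_roc(score, label)$auc,
    as.numeric(pROC::auc(pROC::roc(label, score, quiet = TRUE,
                                   direction = "<"))),
    tolerance = 1e-10)
})

test_that("random scores give AUC near 0.5", {
  set.seed(99)
  score <- runif(20000)
  label <- c(rep(TRUE, 2000), rep(FALSE, 18000))
  expect_lt(abs(lpihn:::.sweep_roc(score, label)$auc - 0.5), 0.02)
})

test_that("confusion metrics match direct arithmetic on hand counts", {
  cm <- lpihn:::.confusion_from_counts(tp = 3, fp = 2, tn = 4, fn = 1)
  expect_equal(cm$sn, 0.75)
  expect_equal(cm$sp, 2 / 3)
  expect_equal(cm$acc, 0.7)
  expect_equal(cm$pre, 0.6)
  expect_equal(cm$mcc, (3 * 4 - 2 * 1) / sqrt(4 * 5 * 6 * 5))

  perfect <- lpihn:::.confusion_from_counts(tp = 5, fp = 0, tn = 5, fn = 0)
  expect_equal(unlist(perfect[c("sn", "sp", "acc", "pre", "mcc")]),
               c(sn = 1, sp = 1, acc = 1, pre = 1, mcc = 1))

  allneg <- lpihn:::.confusion_from_counts(tp = 0, fp = 0, tn = 5, fn = 5)
  expect_equal(allneg$pre, 0)
  expect_equal(allneg$mcc, 0)
  expect_true(allneg$no_positive_predictions)
})

test_that("operating point selection honours the specificity floor", {
  # pooled positives {0.9, 0.8, 0.7, 0.2} and negatives
  # {0.85, 0.75, 0.3, 0.25, 0.15, 0.1}: threshold 0.7 gives
  # TP=3 FP=2 TN=4 FN=1 (Sp = 2/3)
  tr <- make_trials(list(
    list(held_out = "A", candidates = c("A", "N1", "N2"),
         scores = c(0.9, 0.85, 0.75)),
    list(held_out = "B", candidates = c("B", "N3"), scores = c(0.8, 0.30)),
    list(held_out = "C", candidates = c("C", "N4"), scores = c(0.7, 0.25)),
    list(held_out = "D", candidates = c("D", "N5", "N6"),
         scores = c(0.2, 0.15, 0.10))
  ))
  cm <- confusion_metrics(tr, sp_levels = c(2 / 3, 1))
  expect_equal(cm$sp[1], 2 / 3)
  expect_equal(cm$tp[1], 3)
  expect_equal(cm$sn[1], 0.75)
  expect_equal(cm$acc[1], 0.7)
  expect_equal(cm$pre[1], 0.6)
  expect_equal(cm$mcc[1], 10 / sqrt(600))
  expect_true(all(cm$sp >= cm$sp_target - 1e-12))
  # Sp = 1 is reachable via the all-negative operating point
  expect_equal(cm$sp[2], 1)
})

test_that("precision/recall at k count pooled top-k slots", {
  tr <- make_trials(list(
    list(held_out = "A", candidates = c("A", "B", "C", "D", "E"),
         scores = c(5, 4, 3, 2, 1)),
    list(held_out = "B", candidates = c("A", "B", "C", "D", "E"),
         scores = c(5, 4, 3, 2, 1)),
    list(held_out = "E", candidates = c("A", "B", "C", "D", "E"),
         scores = c(5, 4, 3, 2, 1))
  ), n_proteins = 5)
  expect_equal(tr$rank, c(1L, 2L, 5L))
  prk <- precision_recall_at_k(tr)
  expect_equal(prk$recall[2], 2 / 3)
  expect_equal(prk$precision[1], 1 / 3)
  expect_true(all(diff(prk$recall) >= 0))
  expect_equal(prk$recall[5], 1)   # reaches 1 at the max rank
  expect_warning(precision_recall_at_k(tr, k_max = 10), "clamped")

  # all ranked first: precision@1 = recall@1 = 1
  tr1 <- make_trials(list(
    list(held_out = "A", candidates = c("A", "B"), scores = c(2, 1)),
    list(held_out = "C", candidates = c("C", "D"), scores = c(2, 1))
  ))
  prk1 <- precision_recall_at_k(tr1, k_max = 1)
  expect_equal(prk1$precision, 1)
  expect_equal(prk1$recall, 1)
})

test_that("fold enrichment follows N/(2n)", {
  tr <- make_trials(list(
    list(held_out = "A",
         candidates = c("A", sprintf("N%02d", 1:95)),
         scores = c(96, 95:1))
  ))
  expect_equal(tr$n_candidates, 96L)
  expect_equal(fold_enrichment(tr), 48)   # N = 96, n = 1

  # n = N/2 is the random-expectation calibration point
  tr2 <- make_trials(list(
    list(held_out = "C05", candidates = sprintf("C%02d", 1:10),
         scores = 10:1)))
  expect_equal(tr2$rank, 5L)
  expect_equal(fold_enrichment(tr2), 1)

  # mean over trials: (10,1) and (10,5) -> (5 + 1)/2 = 3
  tr3 <- make_trials(list(
    list(held_out = "C01", candidates = sprintf("C%02d", 1:10),
         scores = 10:1),
    list(held_out = "C05", candidates = sprintf("C%02d", 1:10),
         scores = 10:1)
  ))
  expect_equal(fold_enrichment(tr3), 3)
})

test_that("percentile retrieval uses ceiling cutoffs and is monotone", {
  tr <- make_trials(list(
    list(held_out = "C001", candidates = sprintf("C%03d", 1:100), scores = 100:1),
    list(held_out = "C002", candidates = sprintf("C%03d", 1:100), scores = 100:1),
    list(held_out = "C050", candidates = sprintf("C%03d", 1:100), scores = 100:1)
  ))
  expect_equal(tr$rank, c(1L, 2L, 50L))
  pc <- percentile_retrieval(tr, c(2, 10, 100))
  expect_equal(pc$count, c(2, 2, 3))
  expect_true(all(diff(pc$count) >= 0))
  expect_equal(percentile_retrieval(tr, 100)$count, nrow(tr))
})
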