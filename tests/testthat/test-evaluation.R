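# LOOCV harness and randomized baseline.

# 3 lncRNAs with {3, 2, 1} partners; the single-partner lncRNA is
# excluded, leaving 5 trials.
three_lnc_fixture <- function() {
  list(
    interactions = tibble::tibble(
      lncrna = c("L1", "L1", "L1", "L2", "L2", "L3"),
      protein = c("P1", "P2", "P3", "P1", "P4", "P2")),
    expression = tibble::tibble(
      lncrna = c("L1", "L2", "L3"),
      t1 = c(1, 2, 5), t2 = c(2, 3, 4), t3 = c(3, 5, 2), t4 = c(4, 4, 1)),
    ppi = tibble::tibble(
      protein_a = c("P1", "P2", "P3"),
      protein_b = c("P2", "P3", "P4"),
      score = c(0.9, 0.8, 0.7))
  )
}

test_that("LOOCV filters single-partner lncRNAs and sizes candidate sets", {
  fx <- three_lnc_fixture()
  trials <- run_loocv(fx$interactions, fx$expression, fx$ppi)
  expect_s3_class(trials, "lpihn_loocv")
  expect_equal(nrow(trials), 5L)
  expect_false("L3" %in% trials$query)
  m <- attr(trials, "n_proteins")
  expect_equal(m, 4L)
  # N = m - (remaining training partners of the query)
  expect_equal(trials$n_candidates,
               m - lengths(trials$seeds))
  # held-out protein is always among (ranked) candidates, never a seed
  for (t in seq_len(nrow(trials))) {
    expect_true(trials$held_out[t] %in% trials$candidates[[t]])
    expect_false(trials$held_out[t] %in% trials$seeds[[t]])
    expect_equal(trials$candidates[[t]][trials$rank[t]], trials$held_out[t])
    expect_true(all(diff(trials$scores[[t]]) <= 0))
  }
})

test_that("LOOCV hygiene: the held-out pair is absent from the trial's model", {
  fx <- three_lnc_fixture()
  trials <- run_loocv(fx$interactions, fx$expression, fx$ppi)
  prep <- lpihn:::.loocv_prep(fx$interactions, fx$expression, fx$ppi)
  params <- rwr_params()
  for (t in seq_len(nrow(trials))) {
    q <- trials$query[t]; p <- trials$held_out[t]
    It <- prep$I
    It[p, q] <- 0L
    expect_equal(It[p, q], 0L)
    expect_equal(sum(prep$I != It), 1L)  # exactly the held-out entry removed
    # the seed set of the rebuilt initial vector excludes the held-out
    y0 <- build_initial_vector(q, It, params$beta)
    expect_equal(unname(y0$u[p]), 0)
    expect_equal(names(which(y0$u > 0)), trials$seeds[[t]])
    # reproducing the trial from the rebuilt matrices gives the same rank
    tm <- build_transition_matrix(prep$sl, prep$sp, It, params$gamma)
    pr <- propagate(tm, y0, params)
    ranked <- rank_candidates(pr, It, q)
    expect_equal(ranked$rank[ranked$protein == p], trials$rank[t])
  }
})

test_that("LOOCV errors when no lncRNA passes the >= 2 partner filter", {
  fx <- degenerate_fixtures()$tiny_2x2
  expect_error(run_loocv(fx$interactions, fx$expression, fx$ppi),
               "at least two")
})

test_that("single-partner fixture is excluded by the filter", {
  fx <- degenerate_fixtures()$single_partner
  trials <- run_loocv(fx$interactions, fx$expression, fx$ppi)
  expect_false("L2" %in% trials$query)
  expect_equal(sort(unique(trials$query)), "L1")
})

test_that("planted structure ranks held-out partners in the top quartile", {
  scn <- generate_scenario(scenario_config())
  trials <- run_loocv(scn$interactions, scn$expression, scn$ppi)
  frac_top_quartile <- mean(trials$rank <= ceiling(trials$n_candidates / 4))
  expect_gt(frac_top_quartile, 0.5)
  # frozen regression value for the default scenario (seed 1)
  expect_equal(roc_auc(trials)$auc, 0.8771246933, tolerance = 1e-8)
})

test_that("ppi_rwr method evaluates the protein-layer baseline", {
  fx <- three_lnc_fixture()
  trials <- run_loocv(fx$interactions, fx$expression, fx$ppi,
                      method = "ppi_rwr")
  expect_equal(nrow(trials), 5L)
  expect_equal(attr(trials, "method"), "ppi_rwr")
})

test_that("randomized baseline is reproducible and near chance", {
  scn <- generate_scenario(scenario_config(n_lncrnas = 20, n_proteins = 15,
                                           n_groups = 3, seed = 3))
  b1 <- randomized_baseline(scn$interactions, scn$expression, scn$ppi,
                            n_reps = 5, seed = 11)
  b2 <- randomized_baseline(scn$interactions, scn$expression, scn$ppi,
                            n_reps = 5, seed = 11)
  expect_identical(b1$rep_auc, b2$rep_auc)   # bit-reproducible
  expect_lt(abs(b1$mean_auc - 0.5), 0.15)    # no-signal expectation
  trials <- run_loocv(scn$interactions, scn$expression, scn$ppi)
  expect_gt(roc_auc(trials)$auc, b1$mean_auc)
  expect_error(
    randomized_baseline(scn$interactions, scn$expression, scn$ppi,
                        n_reps = 0),
    ">= 1")
})

test_that("tidiers and plots summarise a LOOCV run", {
  fx <- three_lnc_fixture()
  trials <- run_loocv(fx$interactions, fx$expression, fx$ppi)
  td <- tidy(trials)
  expect_equal(names(td),
               c("query", "held_out", "rank", "n_candidates",
                 "fold_enrichment"))
  expect_equal(td$fold_enrichment, td$n_candidates / (2 * td$rank))
  gl <- glance(trials)
  expect_equal(gl$n_trials, 5L)
  expect_equal(gl$auc, roc_auc(trials)$auc)
  expect_equal(gl$mean_fold_enrichment, fold_enrichment(trials))
  expect_s3_class(autoplot(trials, type = "roc"), "ggplot")
  expect_s3_class(autoplot(trials, type = "pr"), "ggplot")
  expect_s3_class(autoplot(trials, type = "ranks"), "ggplot")
})
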