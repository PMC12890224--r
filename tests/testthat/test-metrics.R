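test_that("concordance index: worked examples with the censoring exclusion rule", {
  s3 <- survival_table(c("a", "b", "c"), c(1, 2, 3), c(1, 1, 1))
  expect_equal(concordance_index(c(3, 2, 1), s3)$c_index, 1)
  expect_equal(concordance_index(c(3, 1, 2), s3)$c_index, 2 / 3)
  # censoring the middle sample removes its pair as the shorter partner
  sc <- survival_table(c("a", "b", "c"), c(1, 2, 3), c(1, 0, 1))
  r <- concordance_index(c(3, 1, 2), sc)
  expect_equal(r$n_pairs, 2)
  expect_equal(r$c_index, 1)
  # all censored: no comparable pairs
  expect_error(concordance_index(c(1, 2, 3),
    survival_table(c("a", "b", "c"), c(1, 2, 3), c(0, 0, 0))),
    "no comparable pairs")
})

test_that("time-dependent AUC: worked example and degenerate reversal", {
  s3 <- survival_table(c("a", "b", "c"), c(1, 2, 3), c(1, 1, 1))
  # only t = 2 contributes the pair (i=1, j=3)
  r <- time_dependent_auc(c(3, 2, 1), s3)
  expect_equal(r$n_pairs, 1)
  expect_equal(r$auc, 1)
  expect_equal(time_dependent_auc(c(1, 2, 3), s3)$auc, 0)
})

test_that("both metrics agree exactly with exhaustive pair-enumeration oracles", {
  set.seed(59)
  for (rep in 1:25) {
    n <- sample(5:30, 1)
    time <- round(rexp(n), 1)
    event <- rbinom(n, 1, 0.6)
    scores <- round(rnorm(n), 1)        # provoke score ties
    orc <- oracle_cindex(scores, time, event)
    if (!is.null(orc)) {
      surv <- survival_table(paste0("x", 1:n), time, event)
      got <- concordance_index(scores, surv)
      expect_equal(got$n_pairs, orc$n_pairs)
      expect_equal(got$c_index, orc$c_index, tolerance = 1e-12)
    }
    orca <- oracle_auc(scores, time, event)
    if (!is.null(orca)) {
      surv <- survival_table(paste0("x", 1:n), time, event)
      gota <- time_dependent_auc(scores, surv)
      expect_equal(gota$n_pairs, orca$n_pairs)
      expect_equal(gota$auc, orca$auc, tolerance = 1e-12)
      orce <- oracle_auc(scores, time, event, events_only = TRUE)
      if (!is.null(orce))
        expect_equal(time_dependent_auc(scores, surv, "events_only")$auc,
                     orce$auc, tolerance = 1e-12)
    }
  }
})

test_that("metric invariances: monotone transforms, score negation", {
  set.seed(61)
  n <- 40
  time <- rexp(n); event <- rbinom(n, 1, 0.7)
  scores <- rnorm(n)                    # continuous: no ties
  surv <- survival_table(paste0("x", 1:n), time, event)
  ci <- concordance_index(scores, surv)$c_index
  expect_equal(concordance_index(exp(2 * scores), surv)$c_index, ci)
  expect_equal(concordance_index(rank(scores), surv)$c_index, ci)
  auc <- time_dependent_auc(scores, surv)$auc
  expect_equal(time_dependent_auc(exp(scores), surv)$auc, auc)
  # complementarity under negation without ties
  expect_equal(concordance_index(-scores, surv)$c_index, 1 - ci,
               tolerance = 1e-12)
})

test_that("KM stratification: median split, null identity, hand-checked log-rank", {
  # identical outcome multisets in both groups: statistic 0, p = 1
  surv <- survival_table(paste0("x", 1:8),
                         c(1, 2, 3, 4, 1, 2, 3, 4),
                         c(1, 1, 0, 1, 1, 1, 0, 1))
  scores <- c(5, 6, 7, 8, 1, 2, 3, 4)   # split puts twins on either side
  r <- km_logrank(scores, surv)
  expect_equal(as.vector(table(r$group)), c(4, 4))
  expect_lt(r$logrank_stat, 1e-10)
  expect_equal(r$logrank_p, 1, tolerance = 1e-8)

  # groups with events at 1,2 vs 3,4 (no censoring): hand log-rank table
  # gives O-E = 1.5 - (1/2 + 1/3) with variance terms 1/4 + 2/9 + 1/4
  s2 <- survival_table(paste0("y", 1:4), c(1, 2, 3, 4), c(1, 1, 1, 1))
  sc2 <- c(10, 9, 1, 2)
  r2 <- km_logrank(sc2, s2)
  O_E <- (1 - 2 / 4) + (1 - 1 / 3)      # events of high group minus expected
  V <- (2 * 2 * 3) / (16 * 3) + (1 * 2 * 2) / (9 * 2)
  expect_equal(r2$logrank_stat, O_E^2 / V, tolerance = 1e-8)

  # all scores tied at the median: empty high group is fatal
  expect_error(km_logrank(rep(1, 4), s2), "one group is empty")

  # KM curve starts at 1 after the first event only if no earlier event;
  # with no censoring it equals the empirical survival function
  s3 <- survival_table(paste0("z", 1:6), c(1, 2, 3, 4, 5, 6), rep(1, 6))
  r3 <- km_logrank(c(6, 5, 4, 3, 2, 1), s3)
  for (g in names(r3$curves)) {
    cv <- r3$curves[[g]]
    expect_true(all(diff(cv$survival) <= 1e-12))
    emp <- sapply(cv$time, function(t) mean(s3$time[r3$group == g] > t))
    expect_equal(cv$survival, emp, tolerance = 1e-12)
  }
})
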