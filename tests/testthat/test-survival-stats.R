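test_that("median_split follows the strict larger-than rule", {
  expect_equal(median_split(c(a = 1, b = 2, c = 3, d = 4)),
               c(a = "low", b = "low", c = "high", d = "high"))
  # ties at the median go low
  expect_equal(median_split(c(a = 1, b = 2, c = 2, d = 4)),
               c(a = "low", b = "low", c = "low", d = "high"))
  expect_error(median_split(c(a = 1, b = 1, c = 1, d = 1)), "identical")
  expect_error(median_split(c(a = 1, b = 2, c = 3)), "at least 4")
})

test_that("logrank is zero on identical groups and handles zero events", {
  ids <- sprintf("S%d", 1:8)
  surv <- survival_records(ids, rep(c(3, 5, 8, 13), 2), rep(1, 8))
  labels <- stats::setNames(rep(c("a", "b"), each = 4), ids)
  lr <- logrank(labels, surv)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  surv0 <- survival_records(ids, surv$time, rep(0, 8))
  lr0 <- logrank(labels, surv0)
  expect_true(lr0$zero_events)
  expect_equal(lr0$p_value, 1)
})

test_that("logrank risk-set bookkeeping matches a hand-computed O/E table", {
  # A: event 1, censored 4, event 6; B: event 2, censored 3, event 7
  # t=1: n=6 nA=3 dA=1 -> E+=0.5, V+=0.25 ; t=2: n=5 nA=2 -> E+=0.4, V+=0.24
  # t=6: n=2 nA=1 dA=1 -> E+=0.5, V+=0.25 ; t=7: n=1 nA=0 -> nothing
  ids <- sprintf("S%d", 1:6)
  surv <- survival_records(ids, c(1, 4, 6, 2, 3, 7), c(1, 0, 1, 1, 0, 1))
  labels <- stats::setNames(rep(c("a", "b"), each = 3), ids)
  lr <- logrank(labels, surv)
  # the index group is the sort-last level "b": O_b = 2,
  # E_b = total events - E_a = 4 - 1.4 = 2.6, same statistic either way
  expect_equal(lr$observed, 2)
  expect_equal(lr$expected, 2.6)
  expect_equal(lr$statistic, 0.36 / 0.74, tolerance = 1e-12)
})

test_that("logrank agrees with survdiff and the exhaustive permutation oracle", {
  skip_if_not_installed("survival")
  set.seed(21)
  worst <- 0
  for (i in 1:12) {
    n <- sample(6:10, 1)
    ids <- sprintf("S%d", 1:n)
    surv <- survival_records(ids, round(rexp(n, 0.1), 1) + 0.5,
                             rbinom(n, 1, 0.8))
    labels <- stats::setNames(rep("a", n), ids)
    labels[sample(n, floor(n / 2))] <- "b"
    lr <- logrank(labels, surv)
    sd <- survival::survdiff(
      survival::Surv(surv$time, surv$event) ~ labels[surv$sample_id])
    expect_equal(lr$statistic, sd$chisq, tolerance = 1e-8)
    worst <- max(worst, abs(lr$p_value - perm_logrank_p(labels, surv)))
    # label swap invariance
    swapped <- stats::setNames(ifelse(labels == "a", "b", "a"), names(labels))
    expect_equal(logrank(swapped, surv)$statistic, lr$statistic,
                 tolerance = 1e-10)
  }
  # chi-square approximation tracks the exact permutation null at n <= 10
  expect_lt(worst, 0.15)
  # group A events at 1,2,3 and B at 4,5,6, no censoring: the observed
  # split and its mirror are the two most extreme of the 20 assignments,
  # so the exact permutation p is 2/20
  ids <- sprintf("S%d", 1:6)
  surv <- survival_records(ids, 1:6, rep(1, 6))
  labels <- stats::setNames(rep(c("a", "b"), each = 3), ids)
  expect_equal(perm_logrank_p(labels, surv), 0.1)
  expect_lt(logrank(labels, surv)$p_value, 0.05)
})

test_that("Kaplan-Meier estimates follow the product-limit conventions", {
  ids <- sprintf("S%d", 1:4)
  labels <- stats::setNames(rep("g", 4), ids)
  # S(2)=0.75, S(4)=0.5 -> earliest time with S <= 0.5 is 4
  surv <- survival_records(ids, c(2, 4, 6, 8), rep(1, 4))
  expect_equal(km_median(labels, surv)[["g"]], 4)
  # all censored: never reached
  expect_true(is.na(km_median(labels, survival_records(ids, c(2, 4, 6, 8),
                                                       rep(0, 4)))[["g"]]))
  # single subject
  one <- survival_records("S1", 7, 1)
  expect_equal(km_median(c(S1 = "g"), one)[["g"]], 7)
  # estimator is non-increasing and starts from 1
  set.seed(3)
  surv2 <- survival_records(sprintf("S%d", 1:30), rexp(30, 0.1) + 0.1,
                            rbinom(30, 1, 0.7))
  cur <- km_curve(surv2$time, surv2$event)
  expect_true(all(diff(cur$surv) <= 1e-12))
  expect_true(all(cur$surv <= 1))
})

test_that("Cox regression recovers symmetric and tied cases correctly", {
  skip_if_not_installed("survival")
  # identical survival in both groups -> HR 1
  ids <- sprintf("S%d", 1:12)
  surv <- survival_records(ids, rep(c(2, 5, 7, 9, 11, 14), 2),
                           rep(c(1, 1, 0, 1, 1, 1), 2))
  labels <- stats::setNames(rep(c("high", "low"), 6), ids)
  # pair the two groups on identical outcomes
  labels[] <- c(rep("high", 6), rep("low", 6))
  cx <- cox_univariate(labels, surv)
  expect_equal(cx$hr, 1, tolerance = 1e-6)

  set.seed(9)
  for (i in 1:6) {
    n <- 40
    ids <- sprintf("S%d", 1:n)
    tm <- round(rexp(n, 0.08), ifelse(i %% 2 == 0, 0, 1)) + 0.5  # ties when rounded
    ev <- rbinom(n, 1, 0.75)
    labels <- stats::setNames(sample(c("high", "low"), n, TRUE), ids)
    surv <- survival_records(ids, tm, ev)
    if (sum(ev[labels == "high"]) == 0 || sum(ev[labels == "low"]) == 0) next
    for (ties in c("efron", "breslow")) {
      cx <- cox_univariate(labels, surv, ties = ties)
      or <- survival::coxph(
        survival::Surv(tm, ev) ~ I(labels == "high"), ties = ties)
      expect_equal(cx$beta, unname(stats::coef(or)), tolerance = 1e-6)
      expect_equal(cx$se, sqrt(unname(stats::vcov(or)[1, 1])), tolerance = 1e-6)
    }
    # no ties -> Efron equals Breslow
    tmu <- tm + runif(n) * 1e-3
    survu <- survival_records(ids, tmu, ev)
    expect_equal(cox_univariate(labels, survu, "efron")$beta,
                 cox_univariate(labels, survu, "breslow")$beta,
                 tolerance = 1e-10)
  }
})

test_that("Cox direction is consistent with log-rank observed vs expected", {
  set.seed(31)
  for (i in 1:10) {
    sim <- sim_two_group(80, hr = sample(c(0.4, 1, 2.5), 1), seed = 300 + i)
    lr <- logrank(sim$labels, sim$surv)
    cx <- cox_univariate(sim$labels, sim$surv)
    if (abs(lr$observed - lr$expected) < 1e-8) next
    expect_equal(cx$hr > 1, lr$observed > lr$expected)
  }
})

test_that("complete separation is flagged as divergent", {
  ids <- sprintf("S%d", 1:8)
  surv <- survival_records(ids, c(1, 2, 3, 4, 10, 11, 12, 13), rep(1, 8))
  labels <- stats::setNames(rep(c("high", "low"), each = 4), ids)
  cx <- cox_univariate(labels, surv)
  expect_true(cx$divergent)
})
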