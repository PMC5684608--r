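# the six-hour worked timeline: one seizure at hour 5 whose posthorizon ends
# at the coverage end, a positive alarm inside the 60-minute horizon, false
# alarms at hours 1.0 and 2.5
worked_example <- function() {
  list(coverage = cbind(0, 6 * 3600),
       seizures = seizure_annotations("r", 5 * 3600, 6 * 3600 - 600),
       alarms = c(1 * 3600, 2.5 * 3600, 5 * 3600 - 1800),
       horizon_s = 3600)
}

test_that("the six-hour worked timeline yields sens 1, fwt 2 h, np 4 h, spec 0.5", {
  w <- worked_example()
  res <- evaluate_alarms(w$alarms, w$seizures, w$coverage,
                         alarm_config(horizon_s = w$horizon_s))
  expect_identical(res$sensitivity, 1)
  expect_identical(res$fwt_s, 2 * 3600)
  expect_identical(res$np_s, 4 * 3600)
  expect_identical(res$specificity, 0.5)
})

test_that("normal intervals span posthorizon ends to horizon starts, clipped to coverage", {
  cov6 <- cbind(0, 6 * 3600)
  sz <- seizure_annotations("r", 5 * 3600, 6 * 3600 - 600)
  niv <- normal_intervals(sz, 3600, 600, cov6)
  expect_equal(unname(niv), cbind(0, 4 * 3600))
  # no seizures: the whole coverage is normal
  none <- seizure_annotations(character(0), numeric(0), numeric(0))
  expect_equal(unname(normal_intervals(none, 3600, 600, cov6)), unname(cov6))
  # two seizures with horizons swallowing the time between them
  sz2 <- seizure_annotations(c("r", "r"), c(10000, 14000), c(10060, 14060))
  niv2 <- normal_intervals(sz2, 3600, 600, cbind(0, 20000))
  expect_equal(unname(niv2), cbind(c(0, 14660), c(6400, 20000)))
})

test_that("false waiting time clips to the normal interval and unions overlaps", {
  niv <- cbind(0, 4 * 3600)
  expect_equal(false_waiting_time(numeric(0), 3600, niv), 0)
  # 30 minutes before the interval end: contributes only 30 minutes
  expect_equal(false_waiting_time(4 * 3600 - 1800, 3600, niv), 1800)
  # two overlapping windows are not double-counted
  expect_equal(false_waiting_time(c(1000, 2000), 3600, niv), 3600 + 1000)
})

test_that("specificity, sensitivity and FPR handle edge cases per definition", {
  expect_equal(specificity(0, 14400), 1)
  expect_equal(specificity(14400, 14400), 0)
  expect_true(is.na(specificity(100, 0)))
  sz3 <- seizure_annotations(rep("r", 3), c(10000, 20000, 30000),
                             c(10040, 20040, 30040))
  expect_equal(sensitivity(c(9000, 19000), sz3, 3600), 2 / 3)
  expect_equal(sensitivity(numeric(0), sz3, 3600), 0)
  none <- seizure_annotations(character(0), numeric(0), numeric(0))
  expect_true(is.na(sensitivity(c(1, 2), none, 3600)))
  expect_equal(fpr(2, 4), 0.5)
  expect_equal(fpr(0, 4), 0)
  expect_true(is.na(fpr(1, 0)))
})

test_that("FPR counts false alarms after horizon merging", {
  sz <- seizure_annotations("r", 50000, 50040)
  cov <- cbind(0, 54000)
  # three false alarms, the second within the first horizon: 2 after merging
  res <- evaluate_alarms(c(5000, 7000, 20000), sz, cov,
                         alarm_config(horizon_s = 3600))
  expect_equal(res$n_false, 2L)
  expect_equal(res$fpr, 2 / res$evaluated_h)
})

test_that("prediction time uses the earliest positive alarm in the horizon", {
  sz <- seizure_annotations("r", 36000, 36040)
  pt <- prediction_time(c(36000 - 1800, 36000 - 600), sz, 3600)
  expect_equal(pt$per_seizure, 30)
  expect_equal(pt$mean, 30)
  expect_equal(prediction_time(36000 - 600, sz, 3600)$mean, 10)
  none <- prediction_time(numeric(0), sz, 3600)
  expect_length(none$per_seizure, 0L)
  expect_true(is.na(none$mean))
})

test_that("baseline predictors are periodic or seeded-exponential and respect coverage", {
  cov6 <- cbind(0, 6 * 3600)
  expect_equal(baseline_alarms("periodic", 2, cov6), c(2, 4, 6) * 3600)
  p1 <- baseline_alarms("poisson", 1, cov6, seed = 9)
  expect_identical(p1, baseline_alarms("poisson", 1, cov6, seed = 9))
  expect_false(identical(p1, baseline_alarms("poisson", 1, cov6, seed = 10)))
  # alarms landing in gaps are skipped
  covgap <- rbind(cbind(0, 3 * 3600), cbind(5 * 3600, 8 * 3600))
  pa <- baseline_alarms("periodic", 1, covgap)
  expect_false(any(pa > 3 * 3600 & pa < 5 * 3600))
  # law of large numbers: inter-alarm mean near M over ~1000 draws
  long <- cbind(0, 1000 * 3600)
  pp <- baseline_alarms("poisson", 1, long, seed = 17)
  gaps_s <- diff(pp)
  se <- 3600 / sqrt(length(gaps_s))
  expect_lt(abs(mean(gaps_s) - 3600), 3 * se)
})

test_that("specificity conserves fwt/np and responds monotonically to alarms", {
  set.seed(83)
  for (i in 1:20) {
    on <- sort(runif(2, 30000, 80000))
    on <- on[c(TRUE, diff(on) > 10000)]
    sz <- seizure_annotations(rep("r", length(on)), on, on + 50)
    cov <- cbind(0, 90000)
    alarms <- sort(runif(8, 0, 90000))
    cfg <- alarm_config(horizon_s = 3600)
    res <- evaluate_alarms(alarms, sz, cov, cfg)
    if (res$np_s > 0) {
      expect_equal(res$specificity + res$fwt_s / res$np_s, 1, tolerance = 1e-12)
    }
    # one more false alarm never raises specificity
    extra <- runif(1, 1000, 20000)
    res2 <- evaluate_alarms(c(alarms, extra), sz, cov, cfg)
    expect_lte(res2$specificity, res$specificity + 1e-12)
    # a positive alarm never lowers sensitivity
    res3 <- evaluate_alarms(c(alarms, on[1] - 100), sz, cov, cfg)
    expect_gte(res3$sensitivity, res$sensitivity)
  }
})

test_that("interval-union false waiting time equals a one-second brute-force grid", {
  set.seed(91)
  for (i in 1:15) {
    niv <- cbind(c(0, 30000), c(20000, 50000))
    alarms <- sort(round(runif(6, 0, 50000)))
    h <- 3600
    fwt <- false_waiting_time(alarms, h, niv)
    # brute force: mark every second inside some alarm's clipped window
    marks <- logical(50000)
    for (a in alarms) {
      row <- which(niv[, 1] <= a & a < niv[, 2])
      if (!length(row)) next
      to <- min(a + h, niv[row, 2])
      idx <- seq(floor(a), ceiling(to) - 1)
      marks[idx + 1] <- marks[idx + 1] | (idx >= a & idx + 1 <= to)
    }
    brute <- sum(marks)
    expect_equal(fwt, brute, tolerance = 2)
  }
})
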