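test_that("phase summary stratifies by compliance and uses sample moments", {
  log <- make_log(x = c(0, 10, 20, 100), y = c(5, 22, 31, 140),
                  z = c(25, 38, 46, 174))
  # overall TATs 25, 28, 26, 74 with a 60-min guideline
  ps <- phase_summary(log)
  expect_equal(ps$n, c(4L, 3L, 1L))
  expect_equal(ps$percent, c(100, 75, 25))

  two <- make_log(x = c(0, 0), y = c(10, 20), z = c(30, 40))
  ps2 <- phase_summary(two)
  expect_equal(ps2$tat_mean[ps2$stratum == "overall"], 35)
  expect_equal(ps2$tat_sd[ps2$stratum == "overall"], 7.0711, tolerance = 1e-4)

  # all-compliant log: the after-limit stratum is empty with NA moments
  ok <- make_log(x = c(0, 5), y = c(10, 15), z = c(30, 40))
  ps3 <- phase_summary(ok)
  expect_equal(ps3$n[ps3$stratum == "after_limit"], 0L)
  expect_true(is.na(ps3$tat_mean[ps3$stratum == "after_limit"]))

  expect_error(phase_summary(tatbatch:::new_event_log(
    data.frame(sample_id = character(0), x = numeric(0),
               y = numeric(0), z = numeric(0)))), "empty")
})

test_that("phase summary agrees with a direct per-record loop", {
  set.seed(23)
  for (i in 1:10) {
    log <- random_int_log(sample(5:50, 1))
    ps <- phase_summary(log)
    tats <- numeric(0)
    n_within <- 0L
    for (j in seq_len(nrow(log))) {
      tats <- c(tats, log$z[j] - log$x[j])
      if (log$z[j] - log$x[j] <= 60) n_within <- n_within + 1L
    }
    expect_equal(ps$tat_mean[1], mean(tats))
    expect_equal(ps$n[2], n_within)
    expect_equal(ps$n[2] + ps$n[3], ps$n[1])
    expect_equal(ps$percent[2] + ps$percent[3], 100, tolerance = 0.01)
  }
})

test_that("boxplot statistics follow the linear-interpolation convention", {
  bs <- boxplot_stats(1:100)
  expect_equal(bs$median, 50.5)
  expect_equal(bs$q1, 25.75)
  expect_equal(bs$q3, 75.25)

  const <- boxplot_stats(rep(7, 12))
  expect_equal(const$iqr, 0)
  expect_length(const$outliers, 0)

  out <- boxplot_stats(c(1, 2, 3, 4, 100))
  expect_equal(out$outliers, 100)
  expect_equal(out$whisker_high, 4)

  expect_error(boxplot_stats(numeric(0)), "non-empty")
})

test_that("boxplot outliers always lie outside the 1.5 IQR fences", {
  set.seed(29)
  for (i in 1:100) {
    v <- rlnorm(sample(5:200, 1), meanlog = 3, sdlog = 0.8)
    bs <- boxplot_stats(v)
    expect_true(bs$q1 <= bs$median && bs$median <= bs$q3)
    lo <- bs$q1 - 1.5 * bs$iqr
    hi <- bs$q3 + 1.5 * bs$iqr
    expect_true(all(bs$outliers < lo | bs$outliers > hi))
    expect_true(bs$whisker_low >= lo && bs$whisker_high <= hi)
    expect_equal(length(bs$outliers) + sum(v >= lo & v <= hi), bs$n)
  }
})

test_that("duty report computes per-100 rates, deltas, and efficiency gain", {
  counts <- data.frame(
    period = c("2018", "2018", "2019", "2019"),
    duty = c("evening", "night", "evening", "night"),
    total_works = c(40000, 12000, 50000, 15000),
    switched = c(25000, 5000, 5000, 4000)
  )
  rep <- duty_switch_report(counts)
  expect_equal(rep$per_100[rep$period == "2018" & rep$duty == "evening"], 62.5)
  # the 20,000-task reduction against a 50,000 workload: a 40% gain
  ev19 <- rep[rep$period == "2019" & rep$duty == "evening", ]
  expect_equal(ev19$efficiency_gain_pct, 40)
  expect_equal(ev19$delta_per_100, 10 - 62.5)
  expect_true(all(is.na(rep$delta_per_100[rep$period == "2018"])))

  # identical periods: all deltas zero
  same <- counts
  same$period <- rep(c("a", "b"), each = 2)
  same$total_works <- rep(c(100, 200), 2)
  same$switched <- rep(c(10, 20), 2)
  rep2 <- duty_switch_report(same)
  expect_true(all(rep2$delta_per_100[rep2$period == "b"] == 0))
  expect_true(all(rep2$efficiency_gain_pct[rep2$period == "b"] == 0))

  # single duty, single period: one row and no delta columns
  one <- duty_switch_report(data.frame(period = "2019", duty = "night",
                                       total_works = 200, switched = 50))
  expect_equal(nrow(one), 1L)
  expect_equal(one$per_100, 25)
  expect_false("delta_per_100" %in% names(one))

  bad <- data.frame(period = "p", duty = "d", total_works = 10, switched = 20)
  expect_error(duty_switch_report(bad), "invalid counts")
})

test_that("one alert fires per batch, at its effective loading time", {
  log <- event_log(c("A", "B", "C"),
                   x = c(0, 8, 40), y = c(10, 20, 52), z = c(25, 36, 66))
  al <- monitor_alerts(batch_receipts(log, 25))
  expect_equal(al$alert_time, c(25, 65))
  expect_equal(al$sample_ids[[1]], c("A", "B"))
  expect_equal(al$sample_ids[[2]], "C")

  # at M = 0 alerts coincide with the original Receipt-2 times
  al0 <- monitor_alerts(batch_receipts(log, 0))
  expect_equal(al0$alert_time, log$y)

  empty <- tatbatch:::new_event_log(
    data.frame(sample_id = character(0), x = numeric(0),
               y = numeric(0), z = numeric(0)))
  expect_equal(nrow(monitor_alerts(batch_receipts(empty, 10))), 0L)
})

test_that("alert count always equals the task count", {
  set.seed(37)
  for (i in 1:20) {
    log <- random_int_log(sample(2:30, 1))
    M <- sample(0:60, 1)
    b <- batch_receipts(log, M)
    al <- monitor_alerts(b)
    expect_equal(nrow(al), count_tasks(b))
    expect_true(!is.unsorted(al$alert_time))
    expect_equal(sort(unlist(al$sample_ids)), sort(log$sample_id))
  }
})
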