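day_stamps <- function(date, n = 96, interval = 900) {
  as.POSIXct(paste(date, "00:00:00"), tz = "UTC") +
    seq(0, by = interval, length.out = n)
}

test_that("daily_means aggregates full days and flags under-covered ones", {
  ts <- temperature_series(day_stamps("2016-01-01"), rep(30, 96), "S")
  dm <- daily_means(ts)
  expect_equal(dm$mean_c, 30)
  expect_true(dm$complete)

  # half coverage at the default 0.75 threshold: no mean
  ts2 <- temperature_series(day_stamps("2016-01-01", n = 48), rep(30, 48), "S")
  expect_warning(dm2 <- daily_means(ts2), "min_coverage")
  expect_false(dm2$complete)
  expect_true(is.na(dm2$mean_c))

  # full-period daily sinusoid averages out to its midline
  ts3 <- temperature_series(
    day_stamps("2016-01-01"),
    28 + 2 * sin(2 * pi * (0:95) / 96), "S")
  expect_equal(daily_means(ts3)$mean_c, 28, tolerance = 1e-9)
})

test_that("temperature_series validates its invariants", {
  expect_error(temperature_series(character(0), numeric(0), "S"), "empty")
  expect_error(
    temperature_series(day_stamps("2016-01-01", 2)[c(1, 1)], c(30, 30), "S"),
    "strictly increasing")
  expect_error(
    temperature_series(day_stamps("2016-01-01", 2), c(30, 60), "S"),
    "plausibility")
})

test_that("anomaly_series subtracts the MMM and guards site identity", {
  ts <- series_from_daily(c(1, 0, -0.5), mmm = 30.827)
  an <- anomaly_series(daily_means(ts), climatology("S", 30.827))
  expect_equal(an$anomaly_c, c(1, 0, -0.5))
  expect_error(
    anomaly_series(daily_means(ts), climatology("OTHER", 30.827)),
    "site mismatch")

  # element-wise subtraction oracle on random input
  set.seed(11)
  vals <- round(runif(10, -2, 2), 3)
  an2 <- anomaly_series(daily_means(series_from_daily(vals, 27.399)),
                        climatology("S", 27.399))
  expect_equal(an2$anomaly_c, vals, tolerance = 1e-9)
})

anom_df <- function(a, start = as.Date("2016-01-01")) {
  data.frame(date = start + seq_along(a) - 1, anomaly_c = a)
}

test_that("accumulate_dhd matches closed forms and rules", {
  const <- anom_df(rep(0.5, 84))
  res <- accumulate_dhd(const, "all_positive", 84)
  expect_equal(res$dhd[84], 42)
  expect_false(res$partial_window[84])
  expect_true(all(res$partial_window[1:83]))
  expect_equal(accumulate_dhd(const, "noaa_ge1", 84)$dhd[84], 0)
  neg <- anom_df(rep(-0.3, 30))
  expect_equal(accumulate_dhd(neg, "all_positive")$dhd, rep(0, 30))
  expect_equal(accumulate_dhd(neg, "noaa_ge1")$dhd, rep(0, 30))
  expect_error(accumulate_dhd(const, window_days = 0), "window_days")
})

test_that("window edges: age window_days contributes, window_days + 1 does not", {
  a <- c(2, rep(0, 12))
  res <- accumulate_dhd(anom_df(a), "all_positive", window_days = 10)
  expect_equal(res$dhd[10], 2)   # spike is 10 days old at day 10
  expect_equal(res$dhd[11], 0)   # and 11 days old at day 11
})

test_that("DHD matches the brute-force windowed-sum oracle, with gaps", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 120
    dates <- as.Date("2015-11-01") + sort(sample(0:(n + 20), n))
    a <- round(rnorm(n, 0.3, 0.8), 3)
    for (rule in c("all_positive", "noaa_ge1")) {
      res <- accumulate_dhd(data.frame(date = dates, anomaly_c = a),
                            rule, window_days = 30)
      expect_equal(res$dhd, oracle_dhd(dates, a, rule, 30), tolerance = 1e-9)
    }
  }
})

test_that("rule dominance and dhw identity hold on random series", {
  for (seed in 1:10) {
    set.seed(seed)
    a <- rnorm(200, 0.4, 0.9)
    ap <- accumulate_dhd(anom_df(a), "all_positive")
    ge1 <- accumulate_dhd(anom_df(a), "noaa_ge1")
    expect_true(all(ge1$dhd >= 0))
    expect_true(all(ge1$dhd <= ap$dhd + 1e-12))
    expect_equal(ap$dhw * 7, ap$dhd, tolerance = 1e-12)
  }
})

test_that("shift invariance: adding c to temperatures and MMM changes nothing", {
  set.seed(3)
  anoms <- runif(60, -1.5, 1.5)
  base <- heat_stress_profile(series_from_daily(anoms, 30.827),
                              climatology("S", 30.827))
  # temperatures + 3 and MMM + 3: anomalies (and everything downstream) unchanged
  shifted <- heat_stress_profile(series_from_daily(anoms, 30.827 + 3),
                                 climatology("S", 30.827 + 3))
  expect_equal(shifted$anomaly_c, base$anomaly_c, tolerance = 1e-9)
  expect_equal(shifted$dhd, base$dhd, tolerance = 1e-9)
  expect_equal(shifted$dhw, base$dhw, tolerance = 1e-9)
})

test_that("additivity on warm spells separated by at least the window", {
  spell <- rep(0.8, 10)
  gap <- rep(-1, 84)
  res <- accumulate_dhd(anom_df(c(spell, gap, spell)), "all_positive", 84)
  alone <- accumulate_dhd(anom_df(spell), "all_positive", 84)
  expect_equal(res$dhd[10], alone$dhd[10])
  expect_equal(res$dhd[10 + 84 + 10], alone$dhd[10])
})

test_that("dhd_to_dhw and report_dhw follow the reporting conventions", {
  expect_equal(dhd_to_dhw(0), 0)
  expect_equal(dhd_to_dhw(7), 1)
  expect_error(dhd_to_dhw(-1), "non-negative")
  expect_equal(report_dhw(0), 0)
  expect_equal(report_dhw(19.6), 2.8)  # exact multiples stay put
})

test_that("exceedance_summary counts match a brute-force filter", {
  a <- c(rep(0.5, 10), rep(-0.5, 74))
  prof <- heat_stress_profile(series_from_daily(a, 30), climatology("S", 30))
  s <- exceedance_summary(prof)
  expect_equal(s$days_above_mmm, 10)
  expect_equal(s$days_above_threshold, 0)

  a2 <- rep(1.2, 30)
  s2 <- exceedance_summary(
    heat_stress_profile(series_from_daily(a2, 28), climatology("S", 28)))
  expect_equal(s2$days_above_mmm, 30)
  expect_equal(s2$days_above_threshold, 30)

  set.seed(9)
  a3 <- round(runif(100, -1.5, 1.5), 3)
  prof3 <- heat_stress_profile(series_from_daily(a3, 25), climatology("S", 25))
  s3 <- exceedance_summary(prof3)
  expect_equal(s3$days_above_mmm, sum(a3 > 0))
  expect_equal(s3$days_above_threshold, sum(a3 > 1))
  expect_equal(s3$max_anomaly, max(a3), tolerance = 1e-9)
})
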