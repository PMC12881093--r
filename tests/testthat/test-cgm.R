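test_that("trace validation sorts, de-duplicates, drops out-of-range, is idempotent", {
  t0 <- as.POSIXct("2020-01-01", tz = "UTC")
  tr <- make_trace(c(5, 6, 7))
  tr2 <- cgm_trace(tr$participant_id, tr$time, tr$glucose, quiet = TRUE)
  expect_identical(tr2, tr)
  # unsorted input is canonicalized
  tr3 <- cgm_trace("A", t0 + c(600, 0, 300), c(7, 5, 6), quiet = TRUE)
  expect_equal(tr3$glucose, c(5, 6, 7))
  # duplicate timestamp: first occurrence wins
  expect_message(
    d <- cgm_trace("A", t0 + c(0, 0, 300), c(5, 9, 6)), "duplicate")
  expect_equal(d$glucose, c(5, 6))
  # out-of-range reading dropped
  expect_message(
    o <- cgm_trace("A", t0 + c(0, 300, 600), c(5, 99, 6)), "out-of-range")
  expect_equal(o$glucose, c(5, 6))
  expect_error(cgm_trace("A", t0, 5, quiet = TRUE), "fewer than 2")
})

test_that("windowing is half-open at the anchor midnight and idempotent", {
  tr <- make_trace(rep(6, 120 * 24 * 4), start = "2020-01-01", interval_min = 15)
  anchor <- as.Date("2020-01-01") + 120  # trace spans 120 days
  w <- window_trace(tr, anchor, 90)
  # brute-force filter oracle
  end <- as.POSIXct(anchor, tz = "UTC")
  expect_equal(length(w$glucose), sum(tr$time >= end - 90 * 86400 & tr$time < end))
  # reading exactly at anchor midnight is excluded
  tr2 <- make_trace(c(5, 5, 5), start = "2020-03-31", interval_min = 1440)
  w2 <- window_trace(tr2, as.Date("2020-04-01"), 90)
  expect_equal(length(w2$glucose), 1L)
  # idempotence and no-op when everything fits
  w3 <- window_trace(w, anchor, 90)
  expect_identical(w3, w)
  expect_identical(window_trace(tr, as.Date("2020-05-01"), 365)$glucose, tr$glucose)
})

test_that("mean and dispersion use the sample (n-1) convention", {
  expect_equal(mean_glucose(make_trace(rep(5, 10))), 5)
  d0 <- glucose_dispersion(rep(5, 10))
  expect_equal(d0$sd, 0); expect_equal(d0$cv, 0)
  d1 <- glucose_dispersion(c(4, 6))
  expect_equal(round(d1$sd, 4), 1.4142)
  expect_equal(round(d1$cv, 2), 28.28)
  d2 <- glucose_dispersion(c(3, 5, 7))
  expect_equal(d2$sd, 2)
  expect_equal(d2$cv, 40)
  expect_error(glucose_dispersion(5), "two readings")
})

test_that("band percentages follow the closed/strict boundary convention", {
  expect_equal(time_in_band(rep(5, 4), 3.9, 10), 100)
  expect_equal(time_in_band(rep(5, 4), 3.9, 7.8), 100)
  expect_equal(time_above(rep(5, 4), 10), 0)
  expect_equal(time_below(rep(5, 4), 3.9), 0)
  v <- c(3.5, 5.0, 8.5, 12.0)
  expect_equal(time_below(v, 3.9), 25)
  expect_equal(time_in_band(v, 3.9, 7.8), 25)
  expect_equal(time_in_band(v, 3.9, 10), 50)
  expect_equal(time_above(v, 10), 25)
  # boundary values land in TIR, not TAR/TBR
  b <- c(10.0, 3.9)
  expect_equal(time_in_band(b, 3.9, 10), 100)
  expect_equal(time_above(b, 10), 0)
  expect_equal(time_below(b, 3.9), 0)
})

test_that("band partition and TITR <= TIR hold on random traces", {
  set.seed(42)
  for (i in 1:200) {
    v <- runif(sample(5:60, 1), 0.6, 20)
    s <- summarize_trace(make_trace(v))
    expect_equal(s$tbr + s$tir + s$tar, 100, tolerance = 1e-9)
    expect_lte(s$titr, s$tir)
    expect_equal(s$cv, 100 * s$sd / s$ag, tolerance = 1e-12)
  }
})

test_that("summaries compose the tested parts and count wear", {
  n <- 90 * 288
  s <- summarize_trace(make_trace(rep(10.3, n)), window_days = 90)
  expect_equal(s$ag, 10.3)
  expect_equal(round(s$ugmi_ifcc, 2), 63.69)
  expect_equal(s$tir, 0)  # 10.3 sits above the 10 mmol/l ceiling
  expect_equal(s$tar, 100)
  expect_equal(s$wear_pct, 100)
  # half the readings -> wear 50%
  half <- make_trace(rep(7, n / 2), interval_min = 10)
  half$nominal_interval <- 5
  expect_equal(summarize_trace(half, window_days = 90)$wear_pct, 50)
  expect_equal(summarize_trace(half, window_days = 90)$tir, 100)
})

test_that("summarize is invariant to reading arrival order", {
  set.seed(7)
  v <- runif(500, 3, 15)
  t0 <- as.POSIXct("2020-01-01", tz = "UTC")
  times <- t0 + (seq_along(v) - 1) * 300
  perm <- sample(length(v))
  a <- summarize_trace(cgm_trace("A", times, v, quiet = TRUE))
  b <- summarize_trace(cgm_trace("A", times[perm], v[perm], quiet = TRUE))
  expect_equal(a, b)
})

test_that("sufficiency filter reports machine-readable reasons", {
  full <- make_trace(rep(6, 90 * 288))
  expect_true(sufficiency_filter(full, window_days = 90)$pass)
  short <- make_trace(rep(6, 5 * 288))
  f1 <- sufficiency_filter(short, window_days = 90)
  expect_false(f1$pass); expect_equal(f1$reason, "min_days")
  # 90-day span at 40% retention
  set.seed(1)
  keep <- runif(90 * 288) < 0.4
  keep[c(1, 90 * 288)] <- TRUE
  t0 <- as.POSIXct("2020-01-01", tz = "UTC")
  sparse <- cgm_trace("A", (t0 + (0:(90 * 288 - 1)) * 300)[keep],
                      rep(6, sum(keep)), quiet = TRUE)
  f2 <- sufficiency_filter(sparse, window_days = 90)
  expect_false(f2$pass); expect_equal(f2$reason, "min_wear")
  empty <- window_trace(full, as.Date("1990-01-01"), 30)
  expect_equal(sufficiency_filter(empty)$reason, "empty")
})

# build a record with explicit per-visit windows of constant glucose
record_fixture <- function(group = "control", visit_dates, hba1c, levels,
                           diagnosis = as.Date(NA), days = 30,
                           interval_min = 10) {
  stopifnot(length(visit_dates) == length(levels))
  per_day <- 1440 / interval_min
  secs <- unlist(lapply(seq_along(visit_dates), function(i) {
    t0 <- as.numeric(as.POSIXct(visit_dates[i] - days, tz = "UTC"))
    t0 + (seq_len(days * per_day) - 1) * interval_min * 60
  }))
  glucose <- rep(levels, each = days * per_day)
  participant_record("R1", group,
                     data.frame(date = visit_dates, hba1c = hba1c),
                     cgm_trace("R1", as.POSIXct(secs, tz = "UTC",
                                                origin = "1970-01-01"),
                               glucose, interval_min, quiet = TRUE),
                     diagnosis)
}

test_that("participant aggregation averages HbA1c and censors at diagnosis", {
  dates <- as.Date(c("2020-03-01", "2020-06-01", "2020-09-01"))
  rec <- record_fixture("control", dates, c(55, 57, 59), c(6, 8, 10))
  row <- participant_aggregate(rec, window_days = 30, min_days = 10)
  expect_equal(row$hba1c, 57)
  expect_equal(row$outcome, 0L)
  expect_equal(row$ag, 8)  # three equal-length constant windows
  # case: visits on/after diagnosis are discarded entirely
  rec2 <- record_fixture("case", dates, c(55, 57, 59), c(6, 8, 10),
                         diagnosis = as.Date("2020-06-01"))
  row2 <- participant_aggregate(rec2, window_days = 30, min_days = 10)
  expect_equal(row2$hba1c, 55)
  expect_equal(row2$ag, 6)
  expect_equal(row2$outcome, 1L)
  # no pre-diagnosis visit -> excluded sentinel with reason
  rec3 <- record_fixture("case", dates, c(55, 57, 59), c(6, 8, 10),
                         diagnosis = as.Date("2020-01-15"))
  excl <- participant_aggregate(rec3, window_days = 30, min_days = 10)
  expect_true(is_excluded(excl))
  expect_match(excl$reason, "no pre-diagnosis")
})

test_that("pooled aggregation equals brute-force recomputation on random fixtures", {
  set.seed(11)
  for (i in 1:100) {
    k <- sample(1:3, 1)
    gap <- 40
    dates <- as.Date("2020-01-01") + 35 + (0:(k - 1)) * gap + sample(0:4, k, TRUE)
    levels <- runif(k, 5, 12)
    rec <- record_fixture(sample(c("case", "control"), 1), dates,
                          runif(k, 40, 80), levels,
                          diagnosis = dates[k] + sample(1:30, 1),
                          days = 30, interval_min = 60)
    row <- participant_aggregate(rec, window_days = 30, min_days = 10)
    # brute force: pool windows of pre-diagnosis visits, censor, recompute
    keep_visits <- if (rec$group == "case") {
      rec$visits$date < rec$diagnosis_date
    } else rep(TRUE, k)
    vals <- NULL
    for (j in which(keep_visits)) {
      w <- window_trace(rec$trace, rec$visits$date[j], 30)
      ok <- if (rec$group == "case") {
        w$time < as.POSIXct(rec$diagnosis_date, tz = "UTC")
      } else rep(TRUE, length(w$time))
      vals <- c(vals, w$glucose[ok])
    }
    expect_equal(row$ag, mean(vals), tolerance = 1e-12)
    expect_equal(row$sd, sd(vals), tolerance = 1e-12)
    expect_equal(row$tir, 100 * mean(vals >= 3.9 & vals <= 10), tolerance = 1e-12)
    expect_equal(row$ugmi, ugmi(mean(vals)), tolerance = 1e-12)
    expect_equal(row$hba1c, mean(rec$visits$hba1c[keep_visits]), tolerance = 1e-12)
  }
})

test_that("feature tables collect rows and list exclusions", {
  dates <- as.Date(c("2020-03-01", "2020-06-01"))
  good <- record_fixture("control", dates, c(50, 52), c(7, 9))
  bad <- record_fixture("case", dates, c(50, 52), c(7, 9),
                        diagnosis = as.Date("2020-01-01"))
  bad$id <- "R2"
  ft <- build_feature_table(list(good, bad), window_days = 30, min_days = 10)
  expect_equal(nrow(ft), 1L)
  expect_equal(attr(ft, "excluded")$participant_id, "R2")
  expect_false(anyNA(ft[feature_names()]))
})
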