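test_that("the default thresholds state the indoor standard field-for-field", {
  t <- default_thresholds()
  hi <- setNames(t$hi, t$variable)
  expect_identical(hi[["co"]], 9)
  expect_identical(hi[["co2"]], 900)
  expect_identical(hi[["smoke"]], 0.40)
  expect_identical(hi[["temperature"]], 25)
  expect_identical(hi[["humidity"]], 60)
  expect_true(all(t$lo <= t$hi))
  lo <- setNames(t$lo, t$variable)
  expect_identical(unname(lo[c("co", "co2", "smoke")]), c(0, 0, 0))
})

test_that("heart-rate bounds enter the set only when configured", {
  expect_false("heart_rate" %in% default_thresholds()$variable)
  t <- default_thresholds(hr_range = c(80, 180))
  expect_true("heart_rate" %in% t$variable)
  expect_error(default_thresholds(hr_range = c(180, 80)), "lo <= hi")
})

test_that("reading validation rejects the documented failure modes only", {
  expect_true(validate_reading(make_reading())$valid)

  v <- validate_reading(make_reading(co2 = NA))
  expect_false(v$valid); expect_equal(v$reason, "missing-field")

  v <- validate_reading(make_reading(humidity = 135))
  expect_false(v$valid); expect_equal(v$reason, "out-of-physical-range")

  v <- validate_reading(make_reading(co = -3))
  expect_false(v$valid); expect_equal(v$reason, "out-of-physical-range")

  v <- validate_reading(make_reading(smoke = Inf))
  expect_false(v$valid); expect_equal(v$reason, "non-finite")
})

test_that("a clean generated day passes validation in full, and accepted plus rejected is conserved", {
  g <- gen_sensor_stream(stream_scenario(n_days = 1, seed = 4))
  vr <- validate_readings(g$readings)
  expect_equal(nrow(vr), 720)
  expect_true(all(vr$valid))

  gc <- gen_sensor_stream(stream_scenario(n_days = 1, corrupt_frac = 0.05, seed = 4))
  vc <- validate_readings(gc$readings)
  expect_equal(sum(vc$valid) + sum(!vc$valid), nrow(gc$readings))
  expect_true(all(!vc$valid[gc$corrupted]))  # every corrupted row is caught
})

test_that("duplicate timestamps within a home keep the first reading only", {
  r <- do.call(rbind, lapply(c(0, 120, 120, 240), function(ts)
    as.data.frame(make_reading(timestamp = ts))))
  vr <- validate_readings(r)
  expect_equal(vr$valid, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(vr$reason[3], "duplicate-timestamp")
})

test_that("sampling arithmetic follows the 120-second cadence", {
  expect_identical(expected_sample_count(86400), 720L)
  expect_identical(expected_sample_count(90 * 86400), 64800L)
  expect_identical(expected_sample_count(0), 0L)
  expect_identical(expected_sample_count(239), 1L)
  expect_error(expected_sample_count(-1), "nonnegative")
  # schedule consistency over whole days
  for (k in c(1, 3, 7, 30)) {
    expect_identical(expected_sample_count(k * 86400), 720L * as.integer(k))
  }
})

test_that("range flags use closed intervals and honour HR indeterminacy", {
  t <- default_thresholds(hr_range = c(80, 180))

  fl <- out_of_range_flags(make_reading(), 120, t)
  expect_false(any(fl, na.rm = TRUE))
  expect_false(is.na(fl[["heart_rate"]]))

  # boundary value is acceptable: 25.0 C exactly at the maximum is in range
  fl <- out_of_range_flags(make_reading(temperature = 25.0), 120, t)
  expect_false(fl[["temperature"]])
  fl <- out_of_range_flags(make_reading(temperature = 25.001), 120, t)
  expect_true(fl[["temperature"]])

  fl <- out_of_range_flags(make_reading(co2 = 950), 120, t)
  expect_true(fl[["co2"]])
  expect_false(any(fl[setdiff(names(fl), "co2")], na.rm = TRUE))

  # invalid pulse estimate: indeterminate, never out-of-range
  bad_hr <- structure(list(bpm = 0, valid = FALSE), class = "hr_estimate")
  fl <- out_of_range_flags(make_reading(), bad_hr, t)
  expect_true(is.na(fl[["heart_rate"]]))

  # no pulse channel at all: also indeterminate
  fl <- out_of_range_flags(make_reading(), NULL, t)
  expect_true(is.na(fl[["heart_rate"]]))
})

test_that("a missing threshold for a present variable is an error", {
  t4 <- threshold_set(c("temperature", "humidity", "co", "co2"),
                      c(16, 30, 0, 0), c(25, 60, 9, 900))
  expect_error(out_of_range_flags(make_reading(), NULL, t4), "smoke")
  t5 <- default_thresholds()  # no heart_rate row
  expect_error(out_of_range_flags(make_reading(), 120, t5), "heart_rate")
})

test_that("raising a variable's ceiling never creates a flag", {
  withr::with_seed(8, {
    for (i in 1:25) {
      r <- make_reading(temperature = runif(1, 10, 35),
                        humidity = runif(1, 20, 90),
                        co = runif(1, 0, 15), co2 = runif(1, 300, 1500),
                        smoke = runif(1, 0, 1))
      t1 <- default_thresholds()
      bump <- sample(t1$variable, 1)
      t2 <- t1
      t2$hi[t2$variable == bump] <- t2$hi[t2$variable == bump] + runif(1, 0, 500)
      f1 <- out_of_range_flags(r, NULL, t1)
      f2 <- out_of_range_flags(r, NULL, t2)
      expect_true(!isTRUE(f2[[bump]]) || isTRUE(f1[[bump]]))
    }
  })
})
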