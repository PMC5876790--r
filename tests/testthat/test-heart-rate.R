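sine_source <- function(f, n = 1800, fs = 30) {
  matrix(sin(2 * pi * f * (0:(n - 1)) / fs), ncol = 1)
}

test_that("the default band maps [0.75, 4] Hz onto [45, 240] bpm", {
  cfg <- hr_config()
  expect_identical(60 * cfg$band, c(45, 240))
  # returned bpm can never leave 60 * band: peak search is band-restricted
  for (f in c(0.2, 1.2, 6)) {     # below band, inside, above
    est <- estimate_heart_rate(sine_source(f), 30)
    expect_gte(est$bpm, 45); expect_lte(est$bpm, 240)
  }
})

test_that("a 1.2 Hz component reads as 72 bpm", {
  est <- estimate_heart_rate(sine_source(1.2), 30)
  expect_equal(est$bpm, 72, tolerance = 0.005)
  expect_equal(est$bpm, 60 * est$peak_frequency)
  expect_true(est$valid)
})

test_that("band arguments are validated", {
  s <- sine_source(1.2)
  expect_error(estimate_heart_rate(s, 30, band = c(4, 0.75)), "band")
  expect_error(estimate_heart_rate(s, 30, band = c(0.75, 20)), "band")
  expect_error(estimate_heart_rate(s, 30, band = c(0, 4)), "band")
})

test_that("component selection modes behave and break ties deterministically", {
  fs <- 30
  strong <- sine_source(1.5)
  weak <- 0.2 * sine_source(2.5)
  S <- cbind(weak, strong, weak)
  est <- estimate_heart_rate(S, fs, selection = "max-inband-peak")
  expect_equal(est$component_used, 2L)
  expect_equal(est$bpm, 90, tolerance = 0.05)
  est_fx <- estimate_heart_rate(S, fs, selection = "fixed-index", component = 3)
  expect_equal(est_fx$component_used, 3L)
  expect_equal(est_fx$bpm, 150, tolerance = 0.05)
  # exact tie between identical components resolves to the lowest index
  S_tie <- cbind(strong, strong, weak)
  expect_equal(estimate_heart_rate(S_tie, fs)$component_used, 1L)
})

test_that("the validity gate reflects the spectral prominence requirement", {
  s <- sine_source(1.2)
  expect_true(estimate_heart_rate(s, 30, min_peak_ratio = 0)$valid)
  expect_false(estimate_heart_rate(s, 30, min_peak_ratio = Inf)$valid)
  # a clean tone passes the default 2x-median gate by a wide margin
  expect_true(estimate_heart_rate(s, 30)$valid)
})

test_that("spectral peak matches an independent brute-force DFT argmax", {
  fs <- 30; n <- 200; n_fft <- 1024; band <- c(0.75, 4)
  for (s in 1:10) {
    x <- withr::with_seed(300 + s, {
      f0 <- runif(1, 0.8, 3.8)
      sin(2 * pi * f0 * (0:(n - 1)) / fs) + rnorm(n, sd = 0.5)
    })
    est <- estimate_heart_rate(matrix(x, ncol = 1), fs, n_fft = n_fft)
    expect_equal(est$peak_frequency, brute_force_peak(x, fs, n_fft, band))
  }
})

test_that("pipeline output is invariant to channel scale and source gauge", {
  sc <- trace_scenario(true_bpm = 110, seed = 21)
  g <- gen_rgb_trace(sc)
  cfg <- hr_config(seed = 21)
  est <- hr_pipeline(g$trace, cfg)

  # positive rescaling of all channels changes nothing after standardization
  tr2 <- rgb_trace(3.7 * g$trace$red, 3.7 * g$trace$green, 3.7 * g$trace$blue,
                   g$trace$sampling_rate)
  est2 <- hr_pipeline(tr2, cfg)
  expect_equal(est2$bpm, est$bpm)

  # sign flips and permutations of the unmixed sources leave the
  # max-inband-peak estimate unchanged
  fit <- attr(est, "fit")
  S <- fit$sources
  flipped <- S %*% diag(c(-1, 1, -1))
  permuted <- S[, c(3, 1, 2)]
  e_ref <- estimate_heart_rate(S, 30)
  expect_equal(estimate_heart_rate(flipped, 30)$bpm, e_ref$bpm)
  expect_equal(estimate_heart_rate(permuted, 30)$bpm, e_ref$bpm)
})

test_that("the pipeline recovers ground-truth heart rate from noisy mixtures", {
  errs <- vapply(1:6, function(s) {
    bpm <- withr::with_seed(400 + s, runif(1, 50, 220))
    g <- gen_rgb_trace(trace_scenario(true_bpm = bpm, snr_db = 6, seed = s))
    abs(hr_pipeline(g$trace, hr_config(seed = s))$bpm - bpm)
  }, numeric(1))
  expect_lte(median(errs), 2)
})

test_that("stage failures carry the stage name", {
  tr <- rgb_trace(rnorm(60), rnorm(60), rnorm(60), 30)  # 2 s: too short
  expect_error(hr_pipeline(tr, hr_config(window_s = 1)), "\\[ica\\]")
  expect_error(hr_pipeline(tr, hr_config(window_s = 10)), "\\[preprocess\\]")
})
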