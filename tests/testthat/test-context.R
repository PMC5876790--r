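test_that("risk-profile encoding matches the study's numeric scheme", {
  # Home 1: male, term, own room, mother > 20, pacifier, hard surface
  h1 <- encode_profile("male", "no", "no", "no", "yes", "hard", 8)
  expect_equal(unlist(h1[1:6], use.names = FALSE), c(0, 0, 0, 0, 1, 1))
  # Home 5: male, premature, shared room, young mother, pacifier, soft
  h5 <- encode_profile("male", "yes", "yes", "yes", "yes", "soft", 9)
  expect_equal(unlist(h5[1:6], use.names = FALSE), c(0, 1, 1, 1, 1, 0))
})

test_that("the encoding is bijective: flipping one input flips one field", {
  base <- list(sex = "male", premature = "no", shared_room = "no",
               mother_age_le20 = "no", pacifier = "no", bed_surface = "soft")
  flips <- list(sex = "female", premature = "yes", shared_room = "yes",
                mother_age_le20 = "yes", pacifier = "yes", bed_surface = "hard")
  ref <- unlist(do.call(encode_profile, base)[1:6])
  for (f in names(flips)) {
    args <- base; args[[f]] <- flips[[f]]
    enc <- unlist(do.call(encode_profile, args)[1:6])
    expect_equal(sum(enc != ref), 1)
    expect_true(enc[[f]] != ref[[f]])
  }
  expect_error(encode_profile("robot", "no", "no", "no", "no", "soft"), "sex")
  expect_error(encode_profile("male", "no", "no", "no", "no", "squishy"),
               "bed_surface")
})

test_that("context fusion infers occupancy, sleep state and a stable key", {
  prof <- encode_profile("male", "no", "no", "no", "yes", "hard", 8)
  od <- outdoor_context(15, "temperate", 30)
  cuts <- context_cutoffs()

  # quiet and dark: unoccupied
  ctx <- aggregate_context(make_reading(sound = 10, light = 5), 110, prof, od, cuts)
  expect_equal(ctx$occupancy, 0L)
  # loud alone is not enough; both channels must exceed their cutoffs
  expect_equal(aggregate_context(make_reading(sound = 90, light = 5),
                                 110, prof, od, cuts)$occupancy, 0L)
  expect_equal(aggregate_context(make_reading(sound = 90, light = 80),
                                 110, prof, od, cuts)$occupancy, 1L)

  expect_equal(ctx$sleep_state, "asleep")                   # 110 < 120 split
  expect_equal(aggregate_context(make_reading(), 140, prof, od, cuts)$sleep_state,
               "awake")
  bad_hr <- structure(list(bpm = 0, valid = FALSE), class = "hr_estimate")
  expect_equal(aggregate_context(make_reading(), bad_hr, prof, od, cuts)$sleep_state,
               "unknown")

  # identical inputs give identical keys; key fields reflect the inputs
  ctx2 <- aggregate_context(make_reading(sound = 10, light = 5), 110, prof, od, cuts)
  expect_identical(ctx$context_key, ctx2$context_key)
  expect_identical(ctx$context_key, "temperate|0|asleep|mid")
  expect_identical(
    aggregate_context(make_reading(), 110, prof,
                      outdoor_context(28, "warm", 30), cuts)$context_key,
    "warm|0|asleep|high")
})

test_that("generated context labels round-trip through fusion", {
  sc <- stream_scenario(n_days = 1, season = "cold", outdoor_temp = 5, seed = 12)
  g <- gen_sensor_stream(sc)
  prof <- encode_profile("female", "yes", "yes", "no", "yes", "hard", 10)
  keys <- vapply(seq_len(50), function(i) {
    aggregate_context(as.list(g$readings[i, ]), g$hr$bpm[i], prof, g$outdoor,
                      context_cutoffs())$context_key
  }, character(1))
  expect_true(all(startsWith(keys, "cold|")))
  expect_true(all(endsWith(keys, "|low")))   # 5 C is in the low tercile
})

test_that("learned ranges match an independent median/MAD recomputation", {
  x <- withr::with_seed(77, rnorm(1000, mean = 21, sd = 1))
  hist <- data.frame(context_key = "k", temperature = x)
  std <- default_thresholds()
  map <- learn_personalized_thresholds(hist, std, min_n = 30, k = 3)
  got <- thresholds_for(map, "k")
  want <- oracle_mad_range(x, 3)
  i <- match("temperature", got$variable)
  expect_equal(got$lo[i], want[1], tolerance = 0.3)
  expect_equal(got$hi[i], want[2], tolerance = 0.3)
  expect_equal(attr(got, "provenance"), "personalized")
})

test_that("zero-spread history still yields a usable band via the MAD floor", {
  hist <- data.frame(context_key = "k", temperature = rep(21, 50))
  map <- learn_personalized_thresholds(hist, default_thresholds(), k = 3)
  got <- thresholds_for(map, "k")
  i <- match("temperature", got$variable)
  expect_lt(got$lo[i], 21)
  expect_gt(got$hi[i], 21)
})

test_that("personalization never relaxes a statutory gas maximum", {
  hist <- data.frame(context_key = "k",
                     co2 = withr::with_seed(5, rnorm(200, 1000, 50)))
  map <- learn_personalized_thresholds(hist, default_thresholds(), k = 3)
  got <- thresholds_for(map, "k")
  expect_lte(got$hi[match("co2", got$variable)], 900)
  # and generally: whatever the history, gas ceilings stay capped
  for (s in 1:5) {
    h <- data.frame(context_key = "k",
                    co = withr::with_seed(s, rexp(100, 1 / 20)),
                    smoke = withr::with_seed(s + 50, rexp(100, 1)))
    m <- thresholds_for(learn_personalized_thresholds(h, default_thresholds()), "k")
    expect_lte(m$hi[match("co", m$variable)], 9)
    expect_lte(m$hi[match("smoke", m$variable)], 0.40)
  }
})

test_that("thin history falls back to the standard set", {
  std <- default_thresholds()
  expect_identical(thresholds_for(learn_personalized_thresholds(
    data.frame()[0, ], std), "anything"), std)
  hist <- data.frame(context_key = "k", temperature = rnorm(10, 21))
  got <- thresholds_for(learn_personalized_thresholds(hist, std, min_n = 30), "k")
  i <- match("temperature", got$variable)
  expect_equal(got$lo[i], std$lo[i])
  expect_equal(got$hi[i], std$hi[i])
})
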