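# Seeded synthetic generators: pulse-bearing RGB traces (and rendered
# frames) under linear instantaneous mixing, and diurnal multivariate
# sensor streams with injected excursions. Every generator is a pure
# function of (scenario, seed) and returns ground truth alongside the data,
# so downstream estimates can be scored without re-deriving truth.

#' Default full-rank mixing matrix
#'
#' Rows mix the (pulse, nuisance, nuisance) sources into the red, green and
#' blue channels; diagonally dominant, condition number well below 20, as a
#' benign stand-in for skin reflectance coupling.
#' @return 3 x 3 numeric matrix.
#' @export
default_mixing <- function() {
  matrix(c(0.9, 0.4, 0.2,
           0.3, 1.0, 0.3,
           0.2, 0.3, 0.8), 3L, 3L, byrow = TRUE)
}

#' Scenario for a synthetic RGB pulse trace
#'
#' The pulse source is a sinusoid at `true_bpm / 60` Hz plus a second
#' harmonic at 0.3x amplitude (the dicrotic component of a
#' photoplethysmographic waveform, enough morphology for spectral-peak
#' estimation). Two nuisance sources are generated per `artifact`:
#' slow baseline wander and white noise (`"none"`), a motion sinusoid
#' (`"sinusoidal-motion"`), or illumination steps (`"step-illumination"`).
#' Channels are `mixing %*% sources` plus white Gaussian sensor noise at
#' `snr_db` decibels per channel.
#'
#' @param true_bpm ground-truth heart rate in `[45, 240]` bpm.
#' @param duration_s trace length in seconds.
#' @param sampling_rate frame rate, Hz.
#' @param mixing full-rank 3 x 3 mixing matrix; sources enter in the order
#'   (nuisance, pulse, nuisance) so identity mixing puts the pulse on the
#'   green channel, where skin pulsatility is strongest.
#' @param artifact list with `type` in `"none"`, `"sinusoidal-motion"`
#'   (fields `freq`, `amp`), `"step-illumination"` (fields `times`,
#'   `magnitudes`).
#' @param snr_db per-channel signal-to-noise ratio in dB; `Inf` = no noise.
#' @param seed integer fixing the realization.
#' @return list of class `trace_scenario`.
#' @export
trace_scenario <- function(true_bpm = 120, duration_s = 60,
                           sampling_rate = 30, mixing = default_mixing(),
                           artifact = list(type = "none"), snr_db = 6,
                           seed = 1L) {
  if (true_bpm < 45 || true_bpm > 240) {
    stop("trace_scenario: true_bpm must lie in [45, 240]", call. = FALSE)
  }
  if (!is.matrix(mixing) || any(dim(mixing) != 3L)) {
    stop("trace_scenario: mixing must be 3 x 3", call. = FALSE)
  }
  if (abs(det(mixing)) < 1e-10) {
    stop("trace_scenario: singular mixing matrix", call. = FALSE)
  }
  if (!artifact$type %in% c("none", "sinusoidal-motion", "step-illumination")) {
    stop("trace_scenario: unknown artifact type", call. = FALSE)
  }
  structure(list(true_bpm = true_bpm, duration_s = duration_s,
                 sampling_rate = sampling_rate, mixing = mixing,
                 artifact = artifact, snr_db = snr_db,
                 seed = as.integer(seed)),
            class = "trace_scenario")
}

#' Generate a synthetic RGB trace with ground truth
#'
#' @param sc a [trace_scenario()].
#' @return list with `trace` (an [rgb_trace()]) and `truth` (list:
#'   `true_bpm`, `sources` — n x 3 matrix, pulse in column 2 —, `mixing`,
#'   `noise_sd`).
#' @export
gen_rgb_trace <- function(sc) {
  stopifnot(inherits(sc, "trace_scenario"))
  n <- round(sc$duration_s * sc$sampling_rate)
  t <- (0:(n - 1L)) / sc$sampling_rate
  f <- sc$true_bpm / 60
  withr::with_seed(sc$seed, {
    pulse <- sin(2 * pi * f * t) + 0.3 * sin(2 * pi * 2 * f * t)
    nuis <- switch(sc$artifact$type,
      "none" = 0.5 * sin(2 * pi * 0.08 * t + stats::runif(1, 0, 2 * pi)),
      "sinusoidal-motion" = sc$artifact$amp *
        sin(2 * pi * sc$artifact$freq * t + stats::runif(1, 0, 2 * pi)),
      "step-illumination" = {
        s <- numeric(n)
        for (i in seq_along(sc$artifact$times)) {
          s[t >= sc$artifact$times[i]] <-
            s[t >= sc$artifact$times[i]] + sc$artifact$magnitudes[i]
        }
        s
      })
    white <- stats::rnorm(n, sd = 0.5)
    S <- cbind(nuis, pulse, white)
    obs <- S %*% t(sc$mixing)  # n x 3, channel j = mixing[j, ] . sources
    noise_sd <- if (is.finite(sc$snr_db)) {
      sqrt(apply(obs, 2L, stats::var) / 10^(sc$snr_db / 10))
    } else c(0, 0, 0)
    for (j in 1:3) obs[, j] <- obs[, j] + stats::rnorm(n, sd = noise_sd[j])
    obs <- sweep(obs, 2L, c(110, 118, 95), `+`)  # pixel-mean offsets
    list(trace = rgb_trace(obs[, 1L], obs[, 2L], obs[, 3L], sc$sampling_rate),
         truth = list(true_bpm = sc$true_bpm, sources = S,
                      mixing = sc$mixing, noise_sd = noise_sd))
  })
}

#' Render a synthetic trace into video frames
#'
#' Background pixels are constant; pixels inside the ROI carry the channel
#' value plus independent per-pixel Gaussian noise, so spatial averaging
#' over the ROI recovers the trace up to noise shrinking as 1/sqrt(pixels).
#'
#' @param sc a [trace_scenario()].
#' @param frame_size `c(height, width)` in pixels.
#' @param roi a [frame_roi()] inside `frame_size`.
#' @param pixel_noise_sd per-pixel noise standard deviation.
#' @param background constant background intensity.
#' @return list with `frames` (list of height x width x 3 arrays), `trace`
#'   and `truth` as in [gen_rgb_trace()].
#' @export
gen_frames <- function(sc, frame_size = c(24L, 32L), roi = frame_roi(9, 7, 24, 18),
                       pixel_noise_sd = 1, background = 64) {
  stopifnot(inherits(sc, "trace_scenario"), inherits(roi, "frame_roi"))
  if (roi$y1 > frame_size[1L] || roi$x1 > frame_size[2L]) {
    stop("gen_frames: roi out of frame bounds", call. = FALSE)
  }
  gt <- gen_rgb_trace(sc)
  M <- trace_matrix(gt$trace)
  n <- nrow(M)
  h <- frame_size[1L]; w <- frame_size[2L]
  ry <- roi$y0:roi$y1; rx <- roi$x0:roi$x1
  npx <- length(ry) * length(rx)
  frames <- withr::with_seed(sc$seed + 1L, lapply(seq_len(n), function(i) {
    fr <- array(background, dim = c(h, w, 3L))
    for (ch in 1:3) {
      fr[ry, rx, ch] <- M[i, ch] +
        if (pixel_noise_sd > 0) stats::rnorm(npx, sd = pixel_noise_sd) else 0
    }
    fr
  }))
  list(frames = frames, trace = gt$trace, truth = gt$truth, roi = roi)
}

#' Default diurnal baselines for the sensor stream generator
#'
#' Per variable: mean `level`, peak amplitude of the 24-h sinusoid, and
#' white-noise standard deviation, chosen as plausible values for an
#' occupied temperate-climate bedroom well inside the indoor standard.
#' @return named list of `c(level, amplitude, sd)` per variable.
#' @export
default_stream_baselines <- function() {
  list(temperature = c(level = 21, amplitude = 1.5, sd = 0.3),
       humidity = c(level = 45, amplitude = 5, sd = 1.5),
       co = c(level = 0.8, amplitude = 0.3, sd = 0.1),
       co2 = c(level = 600, amplitude = 80, sd = 25),
       smoke = c(level = 0.05, amplitude = 0.02, sd = 0.01),
       sound = c(level = 40, amplitude = 25, sd = 5),
       light = c(level = 50, amplitude = 45, sd = 5))
}

#' Scenario for a synthetic environmental sensor stream
#'
#' @param n_days number of monitored days; readings arrive every 120 s
#'   (720 per day).
#' @param baselines see [default_stream_baselines()].
#' @param excursions list of `list(variable, start_s, duration_s,
#'   magnitude)` added on top of the baseline; `variable` may also be
#'   `"heart_rate"`.
#' @param season,outdoor_temp,aqi outdoor context held over the stream.
#' @param hr `c(level, sd)` of the simulated infant heart rate in bpm.
#' @param corrupt_frac fraction of readings corrupted
#'   (missing-completely-at-random nulls and physically impossible spikes)
#'   to exercise validity filtering.
#' @param home_id stream identifier.
#' @param seed integer fixing the realization.
#' @return list of class `stream_scenario`.
#' @export
stream_scenario <- function(n_days = 1, baselines = default_stream_baselines(),
                            excursions = list(), season = "temperate",
                            outdoor_temp = 15, aqi = 30,
                            hr = c(level = 120, sd = 3),
                            corrupt_frac = 0, home_id = "home-1", seed = 1L) {
  span <- n_days * 86400
  for (e in excursions) {
    if (e$start_s < 0 || e$start_s + e$duration_s > span) {
      stop("stream_scenario: excursion outside the stream span", call. = FALSE)
    }
  }
  structure(list(n_days = n_days, baselines = baselines,
                 excursions = excursions, season = season,
                 outdoor_temp = outdoor_temp, aqi = aqi, hr = hr,
                 corrupt_frac = corrupt_frac, home_id = home_id,
                 seed = as.integer(seed)),
            class = "stream_scenario")
}

#' Generate a synthetic sensor stream with ground-truth labels
#'
#' Readings at the 120-s cadence: per variable a diurnal sinusoid plus white
#' noise, excursions added over their windows, then (optionally) a seeded
#' fraction of rows corrupted. `labels` marks, for every row and variable,
#' whether an injected excursion affects it; `corrupted` marks mangled rows.
#'
#' @param sc a [stream_scenario()].
#' @return list: `readings` (data.frame, one row per 120-s instant),
#'   `hr` (data.frame `bpm`, `valid`), `labels` (logical matrix rows x
#'   variables incl. `heart_rate`), `corrupted` (logical vector),
#'   `outdoor` (an [outdoor_context()]).
#' @export
gen_sensor_stream <- function(sc) {
  stopifnot(inherits(sc, "stream_scenario"))
  n <- as.integer(round(sc$n_days * 86400 / SAMPLE_PERIOD_S))
  ts <- (seq_len(n) - 1L) * SAMPLE_PERIOD_S
  phase <- c(temperature = -pi / 2, humidity = pi / 2, co = 0, co2 = -pi / 2,
             smoke = 0, sound = -pi / 2, light = -pi / 2)
  withr::with_seed(sc$seed, {
    cols <- lapply(names(sc$baselines), function(v) {
      b <- sc$baselines[[v]]
      pmax(0, b["level"] + b["amplitude"] * sin(2 * pi * ts / 86400 + phase[[v]]) +
             stats::rnorm(n, sd = b["sd"]))
    })
    names(cols) <- names(sc$baselines)
    readings <- data.frame(timestamp = ts, home_id = sc$home_id, cols,
                           stringsAsFactors = FALSE)
    bpm <- sc$hr[["level"]] + stats::rnorm(n, sd = sc$hr[["sd"]])
    label_vars <- c(names(sc$baselines), "heart_rate")
    labels <- matrix(FALSE, n, length(label_vars),
                     dimnames = list(NULL, label_vars))
    for (e in sc$excursions) {
      idx <- which(ts >= e$start_s & ts < e$start_s + e$duration_s)
      if (e$variable == "heart_rate") {
        bpm[idx] <- bpm[idx] + e$magnitude
      } else {
        readings[[e$variable]][idx] <- readings[[e$variable]][idx] + e$magnitude
      }
      labels[idx, e$variable] <- TRUE
    }
    corrupted <- logical(n)
    if (sc$corrupt_frac > 0) {
      bad <- which(stats::runif(n) < sc$corrupt_frac)
      corrupted[bad] <- TRUE
      for (i in bad) {
        v <- sample(AIR_VARIABLES, 1L)
        if (stats::runif(1) < 0.5) {
          readings[[v]][i] <- NA_real_                   # dropped field
        } else {
          # physically impossible spike for the chosen variable
          readings[[v]][i] <- switch(v, humidity = 135, temperature = -80, -5)
        }
      }
    }
    list(readings = readings,
         hr = data.frame(bpm = bpm, valid = TRUE),
         labels = labels, corrupted = corrupted,
         outdoor = outdoor_context(sc$outdoor_temp, sc$season, sc$aqi))
  })
}
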