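# Independent oracles and small fixture builders shared across tests.

# Brute-force one-sided DFT power via direct summation (no fft), same
# mean-removal / Hann taper / zero-padding conventions as the estimator but
# computed from the definition; returns the in-band argmax frequency.
brute_force_peak <- function(x, fs, n_fft, band) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  xw <- c((x - mean(x)) * w, numeric(n_fft - n))
  ks <- 0:floor(n_fft / 2)
  freqs <- ks * fs / n_fft
  keep <- which(freqs >= band[1] & freqs <= band[2])
  j <- 0:(n_fft - 1)
  pw <- vapply(ks[keep], function(k) {
    Mod(sum(xw * exp(-2i * pi * k * j / n_fft)))^2
  }, numeric(1))
  freqs[keep[which.max(pw)]]
}

# Literal re-statement of the expert classification rules, branch order and
# representation deliberately different from the implementation: count every
# out-of-range value including heart rate.
oracle_situation <- function(air_flags, hr_flag) {
  n_out <- sum(air_flags) + as.integer(hr_flag)
  if (n_out == 6L) return(3L)
  if (hr_flag) return(2L)
  if (sum(air_flags) >= 2L) return(2L)
  if (sum(air_flags) == 1L) return(1L)
  0L
}

# Robust range recomputed from first principles (no stats::mad).
oracle_mad_range <- function(x, k) {
  med <- stats::median(x)
  mad_raw <- stats::median(abs(x - med)) * 1.4826
  c(med - k * mad_raw, med + k * mad_raw)
}

sawtooth <- function(f, t) 2 * (f * t - floor(0.5 + f * t))

# A well-formed mid-range sensor reading
make_reading <- function(...) {
  r <- list(timestamp = 0, home_id = "h1", temperature = 21, humidity = 45,
            co = 1, co2 = 600, smoke = 0.05, sound = 30, light = 20)
  utils::modifyList(r, list(...))
}

# constant-colour frame stack: each frame h x w x 3 filled with `rgb`
make_frames <- function(n, h = 8, w = 8, rgb = c(128, 128, 128)) {
  lapply(seq_len(n), function(i) {
    fr <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) fr[, , ch] <- rgb[ch]
    fr
  })
}

all_flag_combos <- function() {
  g <- expand.grid(temperature = c(FALSE, TRUE), humidity = c(FALSE, TRUE),
                   co = c(FALSE, TRUE), co2 = c(FALSE, TRUE),
                   smoke = c(FALSE, TRUE), heart_rate = c(FALSE, TRUE))
  g[, c("temperature", "humidity", "co", "co2", "smoke", "heart_rate")]
}

# elementwise widest range of two threshold sets over shared variables
union_thresholds <- function(a, b) {
  vars <- a$variable
  lo <- pmin(a$lo, b$lo[match(vars, b$variable)])
  hi <- pmax(a$hi, b$hi[match(vars, b$variable)])
  threshold_set(vars, lo, hi, provenance = "personalized")
}
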