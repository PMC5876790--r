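#' One-sided power spectrum of a source signal
#'
#' Mean-removed, Hann-tapered, zero-padded periodogram: the power spectral
#' density estimate used to locate the pulse frequency. The grid spans
#' `[0, sampling_rate/2]` with resolution `sampling_rate / n_fft`, and the
#' estimate is Parseval-consistent: `sum(power) * df` equals the
#' taper-weighted mean square of the signal.
#'
#' @param source numeric time series (length >= 2).
#' @param sampling_rate sampling frequency in Hz (> 0).
#' @param n_fft FFT length, >= `length(source)`; defaults to the next power
#'   of two at least 8x the signal length, giving a frequency resolution
#'   fine enough for ~0.1 bpm granularity at typical webcam frame rates.
#' @param taper `"hann"` (default) or `"none"`.
#' @return Object of class `power_spectrum`: list with `frequencies` (Hz),
#'   `power` (one-sided PSD, nonnegative), `df`, `n_fft`, `sampling_rate`.
#' @export
component_spectrum <- function(source, sampling_rate, n_fft = NULL,
                               taper = c("hann", "none")) {
  source <- as.numeric(source)
  n <- length(source)
  if (n < 2L) stop("component_spectrum: source length must be >= 2", call. = FALSE)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("component_spectrum: sampling_rate must be > 0", call. = FALSE)
  }
  taper <- match.arg(taper)
  if (is.null(n_fft)) n_fft <- next_pow2(8L * n)
  n_fft <- as.integer(n_fft)
  if (n_fft < n) stop("component_spectrum: n_fft must be >= source length", call. = FALSE)
  w <- if (taper == "hann") hann_window(n) else rep(1, n)
  xw <- (source - mean(source)) * w
  xx <- c(xw, numeric(n_fft - n))
  X <- stats::fft(xx)
  half <- floor(n_fft / 2L)
  idx <- 1:(half + 1L)
  p <- (Mod(X[idx])^2) / (sampling_rate * sum(w^2))
  # one-sided: double all bins except DC (and Nyquist when n_fft is even)
  dbl <- rep(2, length(idx)); dbl[1L] <- 1
  if (n_fft %% 2L == 0L) dbl[length(idx)] <- 1
  p <- p * dbl
  structure(
    list(frequencies = (idx - 1L) * sampling_rate / n_fft, power = p,
         df = sampling_rate / n_fft, n_fft = n_fft,
         sampling_rate = sampling_rate, taper = taper),
    class = "power_spectrum"
  )
}

next_pow2 <- function(n) as.integer(2^ceiling(log2(max(n, 2L))))

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1L)) / (n - 1L)))
}

in_band_peak <- function(spec, band) {
  keep <- which(spec$frequencies >= band[1L] & spec$frequencies <= band[2L])
  if (length(keep) == 0L) {
    stop("estimate_heart_rate: no spectral bins inside the band (n_fft too small?)",
         call. = FALSE)
  }
  pw <- spec$power[keep]
  i <- which.max(pw)  # first maximum = lowest frequency on ties
  list(frequency = spec$frequencies[keep[i]], power = pw[i],
       median_power = stats::median(pw))
}

#' Heart-rate estimate from independent components
#'
#' The pulse frequency is the frequency of highest spectral power within an
#' operating band, by default `[0.75, 4]` Hz, i.e. 45-240 beats per minute —
#' wide enough to cover infant (and adult) heart rates. Either the component
#' with the strongest in-band peak is selected (`"max-inband-peak"`, the
#' default, robust to the arbitrary ordering of ICA outputs) or a fixed
#' component index is used (`"fixed-index"`).
#'
#' An estimate is only marked valid when the selected peak rises at least
#' `min_peak_ratio` times above the median in-band power; a near-flat
#' spectrum (signal lost, face out of frame) must not silently read as a
#' plausible heart rate.
#'
#' @param sources an `ica_fit`, a numeric matrix (columns = components) or a
#'   single numeric vector.
#' @param sampling_rate Hz; taken from an `ica_fit` when omitted.
#' @param band numeric `c(f_lo, f_hi)` in Hz, `0 < f_lo < f_hi <=
#'   sampling_rate / 2`.
#' @param selection `"max-inband-peak"` or `"fixed-index"`.
#' @param component component index used when `selection = "fixed-index"`
#'   (default 2).
#' @param n_fft FFT length passed to [component_spectrum()].
#' @param min_peak_ratio prominence requirement for a valid estimate.
#' @return Object of class `hr_estimate`: `bpm`, `peak_frequency` (Hz),
#'   `peak_power`, `component_used`, `valid`, `band`.
#' @export
estimate_heart_rate <- function(sources, sampling_rate = NULL,
                                band = c(0.75, 4),
                                selection = c("max-inband-peak", "fixed-index"),
                                component = 2L, n_fft = NULL,
                                min_peak_ratio = 2) {
  selection <- match.arg(selection)
  if (inherits(sources, "ica_fit")) {
    if (is.null(sampling_rate)) sampling_rate <- sources$sampling_rate
    S <- sources$sources
  } else if (is.matrix(sources)) {
    S <- sources
  } else {
    S <- matrix(as.numeric(sources), ncol = 1L)
  }
  if (is.null(sampling_rate)) {
    stop("estimate_heart_rate: sampling_rate required", call. = FALSE)
  }
  if (length(band) != 2L || band[1L] <= 0 || band[1L] >= band[2L] ||
      band[2L] > sampling_rate / 2) {
    stop("estimate_heart_rate: band must satisfy 0 < f_lo < f_hi <= sampling_rate/2",
         call. = FALSE)
  }
  k <- ncol(S)
  peaks <- vector("list", k)
  for (j in seq_len(k)) {
    spec <- component_spectrum(S[, j], sampling_rate, n_fft = n_fft)
    peaks[[j]] <- in_band_peak(spec, band)
  }
  j <- if (selection == "fixed-index") {
    if (component < 1L || component > k) {
      stop("estimate_heart_rate: component index out of range", call. = FALSE)
    }
    as.integer(component)
  } else {
    which.max(vapply(peaks, `[[`, numeric(1), "power"))  # ties: lowest index
  }
  pk <- peaks[[j]]
  valid <- is.finite(pk$power) && pk$power >= min_peak_ratio * pk$median_power
  structure(
    list(bpm = 60 * pk$frequency, peak_frequency = pk$frequency,
         peak_power = pk$power, component_used = j, valid = valid,
         band = band),
    class = "hr_estimate"
  )
}

#' @export
print.hr_estimate <- function(x, ...) {
  cat(sprintf("<hr_estimate> %.1f bpm (%.3f Hz, component %d)%s\n",
              x$bpm, x$peak_frequency, x$component_used,
              if (x$valid) "" else " [INVALID: weak spectral peak]"))
  invisible(x)
}

#' Configuration for the heart-rate pipeline
#'
#' @param band operating frequency band in Hz (default `[0.75, 4]`,
#'   i.e. 45-240 bpm).
#' @param selection component selection mode, see [estimate_heart_rate()].
#' @param component fixed component index (used by `"fixed-index"` only).
#' @param window_s detrending window in seconds.
#' @param seed seed for the ICA initialization.
#' @param n_fft_factor zero-padding factor: the FFT length is the next power
#'   of two at least this many times the trace length.
#' @param min_peak_ratio spectral prominence required for a valid estimate.
#' @param min_samples minimum trace length for unmixing (`NULL` = ten
#'   seconds).
#' @return list of class `hr_config`.
#' @export
hr_config <- function(band = c(0.75, 4), selection = "max-inband-peak",
                      component = 2L, window_s = 30, seed = 1L,
                      n_fft_factor = 8L, min_peak_ratio = 2,
                      min_samples = NULL) {
  if (length(band) != 2L || band[1L] <= 0 || band[1L] >= band[2L]) {
    stop("hr_config: band must satisfy 0 < f_lo < f_hi", call. = FALSE)
  }
  structure(list(band = as.numeric(band), selection = selection,
                 component = as.integer(component), window_s = window_s,
                 seed = as.integer(seed), n_fft_factor = as.integer(n_fft_factor),
                 min_peak_ratio = min_peak_ratio, min_samples = min_samples),
            class = "hr_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Full heart-rate estimation pipeline
#'
#' Composition detrend/standardize -> ICA unmixing -> band-limited spectral
#' peak, deterministic given the seed in `config`. Errors raised by a stage
#' are re-signalled with the stage name attached.
#'
#' @param trace an [rgb_trace()] (raw; preprocessing is applied here).
#' @param config an [hr_config()].
#' @return An `hr_estimate` (see [estimate_heart_rate()]) with the `ica_fit`
#'   attached as attribute `"fit"`.
#' @export
hr_pipeline <- function(trace, config = hr_config()) {
  stopifnot(inherits(trace, "rgb_trace"), inherits(config, "hr_config"))
  pre <- with_stage("preprocess", preprocess_trace(trace, config$window_s))
  fit <- with_stage("ica", ica_unmix(pre, seed = config$seed,
                                     min_samples = config$min_samples))
  n_fft <- next_pow2(config$n_fft_factor * length(pre))
  est <- with_stage("estimate", estimate_heart_rate(
    fit, band = config$band, selection = config$selection,
    component = config$component, n_fft = n_fft,
    min_peak_ratio = config$min_peak_ratio))
  attr(est, "fit") <- fit
  est
}
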