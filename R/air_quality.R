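# Indoor air-quality stream: the 120-second multivariate sensor cadence,
# the indoor maximum-concentration standard, validity filtering, and
# per-variable range flags.

AIR_VARIABLES <- c("temperature", "humidity", "co", "co2", "smoke")
MONITORED_VARIABLES <- c(AIR_VARIABLES, "heart_rate")
SAMPLE_PERIOD_S <- 120

# statutory indoor maxima for the monitored pollutants/comfort variables
STANDARD_MAXIMA <- c(co = 9, co2 = 900, smoke = 0.40, temperature = 25,
                     humidity = 60)
# gas maxima that personalization must never relax
GAS_SAFETY_CAPS <- STANDARD_MAXIMA[c("co", "co2", "smoke")]

#' Construct a threshold set
#'
#' A per-variable closed acceptable range `[lo, hi]`: a value exactly at a
#' bound is in range.
#'
#' @param variable character vector of variable names.
#' @param lo,hi numeric bounds, `lo <= hi` elementwise.
#' @param provenance `"standard"` or `"personalized"`.
#' @param context_key optional context label the set applies to.
#' @return data.frame of class `threshold_set` with columns `variable`,
#'   `lo`, `hi`.
#' @export
threshold_set <- function(variable, lo, hi, provenance = "standard",
                          context_key = NA_character_) {
  stopifnot(length(variable) == length(lo), length(lo) == length(hi))
  if (any(lo > hi, na.rm = TRUE)) {
    stop("threshold_set: lo must be <= hi for every variable", call. = FALSE)
  }
  out <- data.frame(variable = as.character(variable), lo = as.numeric(lo),
                    hi = as.numeric(hi), stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  attr(out, "context_key") <- context_key
  class(out) <- c("threshold_set", "data.frame")
  out
}

#' Default indoor acceptable ranges
#'
#' Upper limits follow the maximum concentration levels recommended for
#' indoor environments: CO 9 ppm, CO2 900 ppm, tobacco smoke 0.40 ppm,
#' temperature 25 degrees C, relative humidity 60 %. The standard specifies
#' maxima only; lower bounds default to 0 for the gases and to configurable
#' comfort floors of 16 degrees C and 30 % humidity (cold stress matters
#' clinically but sits outside the printed standard).
#'
#' @param hr_range optional numeric `c(lo, hi)` acceptable heart-rate band
#'   in bpm. There is no published default for an infant; supply one per
#'   deployment (see [load_config()], which defaults to `c(80, 180)`).
#' @param temperature_lo,humidity_lo configurable lower comfort bounds.
#' @return A [threshold_set()] with provenance `"standard"`.
#' @export
default_thresholds <- function(hr_range = NULL, temperature_lo = 16,
                               humidity_lo = 30) {
  vars <- AIR_VARIABLES
  lo <- c(temperature = temperature_lo, humidity = humidity_lo,
          co = 0, co2 = 0, smoke = 0)[vars]
  hi <- STANDARD_MAXIMA[vars]
  if (!is.null(hr_range)) {
    if (length(hr_range) != 2L || hr_range[1L] > hr_range[2L]) {
      stop("default_thresholds: hr_range must be c(lo, hi) with lo <= hi",
           call. = FALSE)
    }
    vars <- c(vars, "heart_rate")
    lo <- c(lo, heart_rate = hr_range[1L])
    hi <- c(hi, heart_rate = hr_range[2L])
  }
  threshold_set(vars, lo, hi, provenance = "standard")
}

threshold_row <- function(tset, var) {
  i <- match(var, tset$variable)
  if (is.na(i)) {
    stop(sprintf("missing threshold for variable '%s'", var), call. = FALSE)
  }
  c(lo = tset$lo[i], hi = tset$hi[i])
}

#' Physical plausibility limits for sensor validation
#'
#' Hard physical bounds (not alert thresholds): readings outside these are
#' instrument or transport errors, never real room conditions.
#' @return named list of `c(lo, hi)` per variable.
#' @export
default_physical_limits <- function() {
  list(temperature = c(-40, 60), humidity = c(0, 100), co = c(0, 1000),
       co2 = c(0, 50000), smoke = c(0, 100))
}

#' Validate one sensor reading
#'
#' The acquisition chain drops packets and occasionally delivers garbage
#' (system failures, connection errors); erroneous records must be removed
#' before any classification. Rejection is a return state, not an error.
#'
#' @param r a list or one-row data.frame with fields `timestamp`,
#'   `temperature`, `humidity`, `co`, `co2`, `smoke` (and optionally
#'   `home_id`, `sound`, `light`).
#' @param physical_limits per-variable plausibility bounds, see
#'   [default_physical_limits()].
#' @return `list(valid = TRUE)` or `list(valid = FALSE, reason = ...,
#'   field = ...)` with reason one of `"missing-field"`, `"non-finite"`,
#'   `"out-of-physical-range"`.
#' @export
validate_reading <- function(r, physical_limits = default_physical_limits()) {
  required <- c("timestamp", AIR_VARIABLES)
  for (f in required) {
    v <- r[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v)) {
      return(list(valid = FALSE, reason = "missing-field", field = f))
    }
    if (!is.numeric(v) || !is.finite(v)) {
      return(list(valid = FALSE, reason = "non-finite", field = f))
    }
  }
  for (f in names(physical_limits)) {
    v <- r[[f]]
    if (is.null(v) || is.na(v)) next
    lim <- physical_limits[[f]]
    if (v < lim[1L] || v > lim[2L]) {
      return(list(valid = FALSE, reason = "out-of-physical-range", field = f))
    }
  }
  list(valid = TRUE)
}

#' Validate a stream of readings
#'
#' Applies [validate_reading()] rowwise and additionally rejects duplicate
#' timestamps within a home (first occurrence kept — deterministic dedup).
#' Accepted plus rejected always equals the input count.
#'
#' @param readings data.frame of sensor readings.
#' @param physical_limits see [default_physical_limits()].
#' @return the input with added columns `valid` (logical) and `reason`
#'   (character, `NA` when valid).
#' @export
validate_readings <- function(readings,
                              physical_limits = default_physical_limits()) {
  n <- nrow(readings)
  valid <- logical(n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    v <- validate_reading(as.list(readings[i, , drop = FALSE]), physical_limits)
    valid[i] <- v$valid
    if (!v$valid) reason[i] <- v$reason
  }
  home <- if ("home_id" %in% names(readings)) readings$home_id else ""
  dup <- duplicated(data.frame(home, readings$timestamp))
  reject_dup <- dup & valid
  valid[reject_dup] <- FALSE
  reason[reject_dup] <- "duplicate-timestamp"
  readings$valid <- valid
  readings$reason <- reason
  readings
}

#' Expected number of sensor samples in a time span
#'
#' The sensor node reports every 120 seconds, i.e. 720 readings per day.
#'
#' @param span_s span in seconds (or a `difftime`).
#' @return integer `floor(span_s / 120)`.
#' @export
expected_sample_count <- function(span_s) {
  if (inherits(span_s, "difftime")) {
    span_s <- as.numeric(span_s, units = "secs")
  }
  if (!is.numeric(span_s) || any(span_s < 0)) {
    stop("expected_sample_count: span must be nonnegative", call. = FALSE)
  }
  as.integer(floor(span_s / SAMPLE_PERIOD_S))
}

#' Per-variable out-of-range flags
#'
#' One flag per monitored variable (`temperature`, `humidity`, `co`, `co2`,
#' `smoke`, `heart_rate`): `TRUE` when the value falls outside its closed
#' acceptable range. An invalid heart-rate estimate (weak spectral peak,
#' face lost) yields an indeterminate (`NA`) flag — camera dropout must not
#' masquerade as bradycardia.
#'
#' @param r a sensor reading (list or one-row data.frame).
#' @param hr an `hr_estimate`, a numeric bpm value, or `NULL` (no pulse
#'   reading at this instant).
#' @param thresholds a [threshold_set()] covering every variable present
#'   (including `heart_rate` when `hr` is given).
#' @return named logical vector over the monitored variables; `NA` for an
#'   indeterminate heart rate.
#' @export
out_of_range_flags <- function(r, hr = NULL, thresholds = default_thresholds()) {
  flags <- stats::setNames(rep(NA, length(MONITORED_VARIABLES)),
                           MONITORED_VARIABLES)
  for (v in AIR_VARIABLES) {
    val <- r[[v]]
    if (is.null(val) || is.na(val)) {
      stop(sprintf("out_of_range_flags: reading lacks variable '%s'", v),
           call. = FALSE)
    }
    b <- threshold_row(thresholds, v)
    flags[v] <- (val < b["lo"]) || (val > b["hi"])
  }
  if (!is.null(hr)) {
    bpm <- if (inherits(hr, "hr_estimate")) hr$bpm else as.numeric(hr)
    hr_valid <- if (inherits(hr, "hr_estimate")) hr$valid else is.finite(bpm)
    if (isTRUE(hr_valid)) {
      b <- threshold_row(thresholds, "heart_rate")
      flags["heart_rate"] <- (bpm < b["lo"]) || (bpm > b["hi"])
    }  # else indeterminate: stays NA
  }
  flags
}
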