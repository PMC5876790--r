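# Context encoding and personalized threshold learning.
#
# Which acceptable range applies at a given instant depends on context: the
# infant's fixed risk profile, the season and outdoor conditions, whether
# anyone is in the room, and whether the infant is asleep. Context is
# discretized into a small key; per-key acceptable ranges are learned
# robustly from history and always intersected with the statutory gas
# maxima.

#' Encode an infant risk profile numerically
#'
#' Deterministic 0/1 encoding of the six main risk factors: sex (0 male,
#' 1 female), prematurity (1 yes), shared room (1 yes), mother aged 20 or
#' under (1 yes), pacifier use (1 yes), bed surface (0 soft, 1 hard).
#'
#' @param sex `"male"`/`"female"` or 0/1.
#' @param premature,shared_room,mother_age_le20,pacifier `"yes"`/`"no"`,
#'   logical, or 0/1.
#' @param bed_surface `"soft"`/`"hard"` or 0/1.
#' @param baby_age_months nonnegative number.
#' @return list of class `context_profile` with the six 0/1 fields plus
#'   `baby_age_months`.
#' @export
encode_profile <- function(sex, premature, shared_room, mother_age_le20,
                           pacifier, bed_surface, baby_age_months = NA_real_) {
  enc <- function(x, zero, one, field) {
    if (is.logical(x)) return(as.integer(x))
    if (is.numeric(x) && x %in% c(0, 1)) return(as.integer(x))
    if (is.character(x)) {
      lx <- tolower(x)
      if (lx == zero) return(0L)
      if (lx == one) return(1L)
    }
    stop(sprintf("encode_profile: unknown category '%s' for field '%s'", x, field),
         call. = FALSE)
  }
  if (!is.na(baby_age_months) && baby_age_months < 0) {
    stop("encode_profile: baby_age_months must be >= 0", call. = FALSE)
  }
  structure(list(
    sex = enc(sex, "male", "female", "sex"),
    premature = enc(premature, "no", "yes", "premature"),
    shared_room = enc(shared_room, "no", "yes", "shared_room"),
    mother_age_le20 = enc(mother_age_le20, "no", "yes", "mother_age_le20"),
    pacifier = enc(pacifier, "no", "yes", "pacifier"),
    bed_surface = enc(bed_surface, "soft", "hard", "bed_surface"),
    baby_age_months = as.numeric(baby_age_months)
  ), class = "context_profile")
}

#' Outdoor context record
#'
#' @param ambient_temp outdoor temperature, degrees C.
#' @param season one of `"cold"`, `"temperate"`, `"warm"`.
#' @param air_quality_index nonnegative ordinal outdoor AQI.
#' @param history_percentile optional percentile of the current outdoor
#'   value against local history.
#' @return list of class `outdoor_context`.
#' @export
outdoor_context <- function(ambient_temp, season = c("temperate", "cold", "warm"),
                            air_quality_index = 0,
                            history_percentile = NA_real_) {
  season <- match.arg(season)
  if (air_quality_index < 0) {
    stop("outdoor_context: air_quality_index must be >= 0", call. = FALSE)
  }
  structure(list(ambient_temp = as.numeric(ambient_temp), season = season,
                 air_quality_index = as.numeric(air_quality_index),
                 history_percentile = as.numeric(history_percentile)),
            class = "outdoor_context")
}

#' Cutoffs used when fusing context
#'
#' @param sound_cutoff,light_cutoff room-occupancy requires sound AND light
#'   above these levels (arbitrary sensor units).
#' @param sleep_hr_split bpm below which a valid heart rate is read as
#'   asleep; no published value exists, the default is configurable.
#' @param temp_breaks outdoor-temperature discretization breakpoints
#'   (degrees C) defining the low/mid/high terciles.
#' @return named list.
#' @export
context_cutoffs <- function(sound_cutoff = 50, light_cutoff = 50,
                            sleep_hr_split = 120, temp_breaks = c(10, 20)) {
  list(sound_cutoff = sound_cutoff, light_cutoff = light_cutoff,
       sleep_hr_split = sleep_hr_split, temp_breaks = sort(temp_breaks))
}

#' Fuse indoor reading, pulse, profile and outdoor context
#'
#' Occupancy is inferred from the sound and light sensors (both above their
#' cutoffs), sleep state from the heart-rate estimate (below the configured
#' split = asleep; invalid estimate = unknown), and the outdoor temperature
#' is discretized into terciles. The canonical `context_key`
#' `season|occupancy|sleep|tercile` indexes the personalized threshold
#' store.
#'
#' @param reading sensor reading (list or one-row data.frame) with optional
#'   `sound` and `light` fields.
#' @param hr an `hr_estimate`, numeric bpm, or `NULL`.
#' @param profile a [encode_profile()] result.
#' @param outdoor an [outdoor_context()].
#' @param cutoffs a [context_cutoffs()] list.
#' @return list of class `context_state` with fields `profile`, `outdoor`,
#'   `occupancy`, `sleep_state`, `context_key`.
#' @export
aggregate_context <- function(reading, hr, profile, outdoor,
                              cutoffs = context_cutoffs()) {
  snd <- reading[["sound"]]; lgt <- reading[["light"]]
  occupancy <- as.integer(
    !is.null(snd) && !is.na(snd) && snd > cutoffs$sound_cutoff &&
    !is.null(lgt) && !is.na(lgt) && lgt > cutoffs$light_cutoff
  )
  bpm <- NA_real_; hr_valid <- FALSE
  if (!is.null(hr)) {
    if (inherits(hr, "hr_estimate")) {
      bpm <- hr$bpm; hr_valid <- isTRUE(hr$valid)
    } else {
      bpm <- as.numeric(hr); hr_valid <- is.finite(bpm)
    }
  }
  sleep_state <- if (!hr_valid) "unknown"
                 else if (bpm < cutoffs$sleep_hr_split) "asleep" else "awake"
  tercile <- cut(outdoor$ambient_temp,
                 breaks = c(-Inf, cutoffs$temp_breaks, Inf),
                 labels = c("low", "mid", "high"))
  key <- paste(outdoor$season, occupancy, sleep_state, as.character(tercile),
               sep = "|")
  structure(list(profile = profile, outdoor = outdoor, occupancy = occupancy,
                 sleep_state = sleep_state, context_key = key),
            class = "context_state")
}

mad_floor_defaults <- c(temperature = 0.1, humidity = 1, co = 0.05,
                        co2 = 10, smoke = 0.01, heart_rate = 1)

#' Learn personalized per-context acceptable ranges
#'
#' For every context key and monitored variable with at least `min_n`
#' validated historical readings, the acceptable range becomes
#' `median +/- k * MAD` (MAD floored at a per-variable resolution `eps` so a
#' zero-spread history still yields a usable band), intersected with hard
#' safety caps: a learned gas maximum (CO, CO2, smoke) never exceeds the
#' statutory indoor standard, gas and humidity floors never drop below 0,
#' and humidity never exceeds 100 %. Contexts or variables with too little
#' history fall back to the standard set unchanged.
#'
#' @param history data.frame of validated readings with a `context_key`
#'   column; recognised variable columns are `temperature`, `humidity`,
#'   `co`, `co2`, `smoke`, and optionally `heart_rate`.
#' @param standard fallback [threshold_set()].
#' @param min_n minimum history size per (context, variable); default 30.
#' @param k spread multiplier (default 3).
#' @param mad_floor named per-variable lower bound on the MAD.
#' @return A `threshold_map`: named list of personalized [threshold_set()]s
#'   keyed by `context_key`, with the standard set stored under
#'   `".default"`. Use [thresholds_for()] to resolve a key.
#' @export
learn_personalized_thresholds <- function(history, standard, min_n = 30, k = 3,
                                          mad_floor = mad_floor_defaults) {
  out <- list(".default" = standard)
  class(out) <- "threshold_map"
  if (is.null(history) || nrow(history) == 0L) return(out)
  if (!"context_key" %in% names(history)) {
    stop("learn_personalized_thresholds: history needs a context_key column",
         call. = FALSE)
  }
  vars <- intersect(standard$variable, names(history))
  for (key in unique(history$context_key)) {
    hk <- history[history$context_key == key, , drop = FALSE]
    lo <- standard$lo; hi <- standard$hi
    names(lo) <- names(hi) <- standard$variable
    for (v in vars) {
      x <- hk[[v]]
      x <- x[is.finite(x)]
      if (length(x) < min_n) next
      med <- stats::median(x)
      spread <- max(stats::mad(x), mad_floor[[v]] %||% 0, na.rm = TRUE)
      lo[v] <- med - k * spread
      hi[v] <- med + k * spread
      if (v %in% names(GAS_SAFETY_CAPS)) {
        hi[v] <- min(hi[v], GAS_SAFETY_CAPS[[v]])
        lo[v] <- max(lo[v], 0)
      }
      if (v == "humidity") { lo[v] <- max(lo[v], 0); hi[v] <- min(hi[v], 100) }
      if (lo[v] > hi[v]) { lo[v] <- hi[v] }  # cap collided with a high median
    }
    out[[key]] <- threshold_set(standard$variable, lo, hi,
                                provenance = "personalized", context_key = key)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve the threshold set for a context key
#'
#' @param map a `threshold_map` from [learn_personalized_thresholds()], or a
#'   plain [threshold_set()] (returned as is).
#' @param context_key character key; unseen keys fall back to the default.
#' @return a [threshold_set()].
#' @export
thresholds_for <- function(map, context_key) {
  if (inherits(map, "threshold_set")) return(map)
  stopifnot(inherits(map, "threshold_map"))
  map[[context_key]] %||% map[[".default"]]
}
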