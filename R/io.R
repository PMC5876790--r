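# File formats, run configuration, the notification sink, and the
# end-to-end monitor composition.

#' Read an RGB trace from CSV or JSONL
#'
#' CSV needs a header with columns `t,r,g,b` (`t` in seconds); JSONL holds
#' one record `{"t":..,"r":..,"g":..,"b":..}` per line. The sampling rate
#' is taken from `sampling_rate` or inferred from the median timestamp
#' spacing.
#'
#' @param path file path; format chosen by extension (`.jsonl` vs CSV) or
#'   forced with `format`.
#' @param sampling_rate Hz, optional.
#' @param format `"auto"`, `"csv"` or `"jsonl"`.
#' @return an [rgb_trace()].
#' @export
read_rgb_trace <- function(path, sampling_rate = NULL,
                           format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  d <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    jsonlite::stream_in(file(path), verbose = FALSE)
  }
  need <- c("t", "r", "g", "b")
  if (!all(need %in% names(d))) {
    stop("read_rgb_trace: expected columns t, r, g, b", call. = FALSE)
  }
  if (is.null(sampling_rate)) {
    sampling_rate <- 1 / stats::median(diff(d$t))
  }
  rgb_trace(d$r, d$g, d$b, sampling_rate, timestamps = d$t)
}

#' Write an RGB trace to CSV or JSONL
#' @param trace an [rgb_trace()].
#' @param path destination path.
#' @param format `"auto"`, `"csv"` or `"jsonl"`.
#' @export
write_rgb_trace <- function(trace, path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  d <- data.frame(t = trace$timestamps, r = trace$red, g = trace$green,
                  b = trace$blue)
  if (format == "csv") {
    utils::write.csv(d, path, row.names = FALSE)
  } else {
    jsonlite::stream_out(d, file(path), verbose = FALSE, digits = NA)
  }
  invisible(path)
}

SENSOR_CSV_MAP <- c(ts = "timestamp", home = "home_id", temp_c = "temperature",
                    rh = "humidity", co_ppm = "co", co2_ppm = "co2",
                    smoke_ppm = "smoke", sound = "sound", light = "light")

#' Read a sensor log (CSV columns `ts,home,temp_c,rh,co_ppm,co2_ppm,
#' smoke_ppm,sound,light`, or JSONL with the same keys)
#' @param path file path.
#' @param format `"auto"`, `"csv"` or `"jsonl"`.
#' @return data.frame with canonical column names (`timestamp`, `home_id`,
#'   `temperature`, ...).
#' @export
read_sensor_log <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  d <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    jsonlite::stream_in(file(path), verbose = FALSE)
  }
  hit <- names(d) %in% names(SENSOR_CSV_MAP)
  names(d)[hit] <- SENSOR_CSV_MAP[names(d)[hit]]
  d
}

#' Write a sensor log
#' @param readings data.frame with canonical column names.
#' @param path destination.
#' @param format `"auto"`, `"csv"` or `"jsonl"`.
#' @export
write_sensor_log <- function(readings, path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  rev_map <- stats::setNames(names(SENSOR_CSV_MAP), SENSOR_CSV_MAP)
  d <- readings
  hit <- names(d) %in% names(rev_map)
  names(d)[hit] <- rev_map[names(d)[hit]]
  if (format == "csv") {
    utils::write.csv(d, path, row.names = FALSE)
  } else {
    jsonlite::stream_out(d, file(path), verbose = FALSE, digits = NA)
  }
  invisible(path)
}

config_defaults <- function() {
  list(
    band = c(0.75, 4),            # Hz; 45-240 bpm operating range
    selection = "max-inband-peak",
    window_s = 30,
    sampling_rate = 30,
    seed = 1L,
    thresholds = list(             # indoor standard maxima + comfort floors
      temperature = c(16, 25), humidity = c(30, 60), co = c(0, 9),
      co2 = c(0, 900), smoke = c(0, 0.40),
      heart_rate = c(80, 180)      # no published infant default; configurable
    ),
    learning = list(min_n = 30, k = 3),
    cutoffs = list(sound_cutoff = 50, light_cutoff = 50,
                   sleep_hr_split = 120, temp_breaks = c(10, 20)),
    notify_level = 2L,             # Alert and Emergency reach the sink
    sink = NULL
  )
}

parse_band <- function(b) {
  if (is.character(b) && length(b) == 1L) {
    b <- as.numeric(strsplit(b, ":", fixed = TRUE)[[1L]])
  }
  b <- as.numeric(b)
  if (length(b) != 2L || any(!is.finite(b)) || b[1L] <= 0 || b[1L] >= b[2L]) {
    stop("config: band must be two increasing positive frequencies (f_lo:f_hi)",
         call. = FALSE)
  }
  b
}

#' Load a run configuration
#'
#' JSON keyed like the defaults; anything absent falls back to the default,
#' unknown top-level keys are rejected by name. An empty file (or `NULL`
#' path) yields the full default configuration.
#'
#' @param path JSON file path or `NULL`.
#' @return list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("load_config: no such file: ", path, call. = FALSE)
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (nzchar(trimws(txt))) {
      user <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
      unknown <- setdiff(names(user), names(cfg))
      if (length(unknown)) {
        stop("load_config: unknown keys: ", paste(unknown, collapse = ", "),
             call. = FALSE)
      }
      for (k in names(user)) {
        cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(user[[k]])) {
          utils::modifyList(cfg[[k]], user[[k]])
        } else user[[k]]
      }
    }
  }
  cfg$band <- parse_band(cfg$band)
  for (v in names(cfg$thresholds)) {
    tv <- as.numeric(cfg$thresholds[[v]])
    if (length(tv) != 2L || tv[1L] > tv[2L]) {
      stop("load_config: threshold for '", v, "' must be c(lo, hi)", call. = FALSE)
    }
    cfg$thresholds[[v]] <- tv
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' Threshold set held in a run configuration
#' @param cfg a [load_config()] result.
#' @return a [threshold_set()] covering the monitored variables.
#' @export
config_thresholds <- function(cfg) {
  vars <- names(cfg$thresholds)
  threshold_set(vars,
                vapply(cfg$thresholds, `[`, numeric(1), 1L),
                vapply(cfg$thresholds, `[`, numeric(1), 2L),
                provenance = "standard")
}

#' Append an alert event to a JSONL notification sink
#'
#' Idempotent per `(timestamp, home_id, class)`: replaying the same event
#' leaves a single record.
#'
#' @param event list with `timestamp`, `home_id`, `class` (0-3),
#'   `triggering_flags`, `message`.
#' @param sink path to the JSONL sink file (created on first write).
#' @return invisibly, `TRUE` if a record was appended.
#' @export
emit_alert <- function(event, sink) {
  stopifnot(is.list(event), !is.null(event$timestamp), !is.null(event$class))
  key <- paste(event$timestamp, event$home_id %||% "", event$class, sep = "|")
  if (file.exists(sink)) {
    prior <- readLines(sink, warn = FALSE)
    for (ln in prior) {
      if (!nzchar(ln)) next
      e <- jsonlite::fromJSON(ln)
      if (paste(e$timestamp, e$home_id %||% "", e$class, sep = "|") == key) {
        return(invisible(FALSE))
      }
    }
  }
  rec <- jsonlite::toJSON(
    list(timestamp = event$timestamp, home_id = event$home_id %||% "",
         class = event$class,
         triggering_flags = as.list(event$triggering_flags %||% character(0)),
         message = event$message %||% ""),
    auto_unbox = TRUE)
  con <- file(sink, open = "a")
  on.exit(close(con))
  writeLines(as.character(rec), con)
  invisible(TRUE)
}

#' Run the full monitoring pipeline over a recorded stream
#'
#' Validates the sensor stream, fuses context per instant, learns
#' personalized thresholds from the stream's own history, classifies every
#' accepted instant under both the context model and the binary baseline,
#' summarizes per home, and writes alert events at or above
#' `cfg$notify_level` to the configured sink (when any).
#'
#' @param readings sensor readings data.frame.
#' @param hr data.frame `bpm`, `valid` aligned with `readings`, or `NULL`.
#' @param profile a [encode_profile()].
#' @param outdoor an [outdoor_context()] (or per-reading list).
#' @param cfg a [load_config()] result.
#' @return list: `series` (classified instants), `summary`
#'   ([evaluate_comparison()]), `alerts` (data.frame of emitted events),
#'   `thresholds` (the learned `threshold_map`).
#' @export
run_monitor <- function(readings, hr = NULL, profile, outdoor,
                        cfg = load_config()) {
  standard <- config_thresholds(cfg)
  cuts <- do.call(context_cutoffs, cfg$cutoffs)
  vr <- with_stage("validate", validate_readings(readings))
  acc <- vr[vr$valid, , drop = FALSE]
  hr_acc <- if (is.null(hr)) NULL else hr[vr$valid, , drop = FALSE]
  # context key per accepted instant, for learning
  keys <- vapply(seq_len(nrow(acc)), function(i) {
    hri <- if (is.null(hr_acc)) NULL else
      if (isTRUE(hr_acc$valid[i])) hr_acc$bpm[i] else NULL
    od <- if (inherits(outdoor, "outdoor_context")) outdoor else outdoor[[i]]
    aggregate_context(as.list(acc[i, , drop = FALSE]), hri, profile, od,
                      cuts)$context_key
  }, character(1))
  hist <- acc
  hist$context_key <- keys
  if (!is.null(hr_acc)) hist$heart_rate <- ifelse(hr_acc$valid, hr_acc$bpm, NA)
  tmap <- with_stage("learn", learn_personalized_thresholds(
    hist, standard, min_n = cfg$learning$min_n, k = cfg$learning$k))
  series <- with_stage("classify", classify_stream(
    vr, hr, profile, outdoor, tmap, baseline = standard, cutoffs = cuts))
  summary <- evaluate_comparison(series)
  notify <- series[series$class >= cfg$notify_level, , drop = FALSE]
  if (!is.null(cfg$sink) && nrow(notify)) {
    for (i in seq_len(nrow(notify))) {
      emit_alert(list(timestamp = notify$timestamp[i],
                      home_id = notify$home_id[i], class = notify$class[i],
                      message = SITUATION_LABELS[as.character(notify$class[i])]),
                 cfg$sink)
    }
  }
  list(series = series, summary = summary, alerts = notify, thresholds = tmap)
}
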