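#' RGB trace: spatially averaged channel means over a tracked face region
#'
#' The raw observation of the remote-photoplethysmography model: at each
#' video frame, the mean red, green and blue intensity over the region of
#' interest (typically the forehead). The cardiovascular pulse modulates the
#' amount of light reflected by facial skin, so these three time series are a
#' linear mixture of the pulse source and nuisance sources (motion,
#' illumination changes).
#'
#' @param red,green,blue numeric vectors of equal length (>= 2), per-frame
#'   spatial mean intensity in arbitrary units.
#' @param sampling_rate frames per second (Hz), > 0.
#' @param timestamps optional numeric vector of frame times in seconds,
#'   strictly increasing; defaults to a regular grid at `sampling_rate`.
#' @return An object of class `rgb_trace`: a list with fields `timestamps`,
#'   `red`, `green`, `blue`, `sampling_rate`.
#' @export
rgb_trace <- function(red, green, blue, sampling_rate, timestamps = NULL) {
  red <- as.numeric(red); green <- as.numeric(green); blue <- as.numeric(blue)
  n <- length(red)
  if (n < 2L || length(green) != n || length(blue) != n) {
    stop("rgb_trace: channels must have equal length >= 2", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("rgb_trace: sampling_rate must be a single positive number", call. = FALSE)
  }
  if (is.null(timestamps)) {
    timestamps <- (seq_len(n) - 1) / sampling_rate
  } else {
    timestamps <- as.numeric(timestamps)
    if (length(timestamps) != n) stop("rgb_trace: timestamps length mismatch", call. = FALSE)
    if (any(diff(timestamps) <= 0)) {
      stop("rgb_trace: timestamps must be strictly increasing", call. = FALSE)
    }
  }
  structure(
    list(timestamps = timestamps, red = red, green = green, blue = blue,
         sampling_rate = sampling_rate),
    class = "rgb_trace"
  )
}

#' @export
print.rgb_trace <- function(x, ...) {
  cat(sprintf("<rgb_trace> %d frames @ %.3g Hz (%.1f s)\n",
              length(x$red), x$sampling_rate,
              length(x$red) / x$sampling_rate))
  invisible(x)
}

#' @export
length.rgb_trace <- function(x) length(x$red)

#' Matrix of trace channels
#'
#' @param trace an [rgb_trace()].
#' @return n x 3 numeric matrix with columns `red`, `green`, `blue`.
#' @export
trace_matrix <- function(trace) {
  stopifnot(inherits(trace, "rgb_trace"))
  cbind(red = trace$red, green = trace$green, blue = trace$blue)
}

#' Region of interest within a frame
#'
#' Pixel coordinates are 1-based and inclusive; `x` indexes columns, `y`
#' indexes rows, and the region covers columns `x0:x1` by rows `y0:y1`.
#'
#' @param x0,y0,x1,y1 integer pixel coordinates with `x0 < x1`, `y0 < y1`.
#' @param frame_index optional ordinal of the frame this ROI belongs to.
#' @return list of class `frame_roi`.
#' @export
frame_roi <- function(x0, y0, x1, y1, frame_index = NA_integer_) {
  co <- c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  if (any(!is.finite(co)) || any(co < 1) || x0 >= x1 || y0 >= y1) {
    stop("frame_roi: require 1 <= x0 < x1 and 1 <= y0 < y1", call. = FALSE)
  }
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1),
                 frame_index = as.integer(frame_index)),
            class = "frame_roi")
}

#' Extract an RGB trace from video frames
#'
#' Separates each frame into its three colour channels and takes the
#' arithmetic spatial mean over the region-of-interest pixels, producing the
#' red, green and blue signals that feed the pulse estimator.
#'
#' @param frames list of numeric arrays of dimension `height x width x 3`.
#' @param rois a single [frame_roi()] applied to every frame, or a list with
#'   one ROI per frame.
#' @param sampling_rate frame rate in Hz.
#' @return An [rgb_trace()] of the same length as `frames`.
#' @export
extract_rgb_trace <- function(frames, rois, sampling_rate) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop("extract_rgb_trace: empty frame sequence", call. = FALSE)
  }
  n <- length(frames)
  if (inherits(rois, "frame_roi")) rois <- rep(list(rois), n)
  if (length(rois) != n) {
    stop("extract_rgb_trace: need one ROI per frame", call. = FALSE)
  }
  out <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    fr <- frames[[i]]
    roi <- rois[[i]]
    d <- dim(fr)
    if (is.null(d) || length(d) != 3L || d[3L] != 3L) {
      stop(sprintf("extract_rgb_trace: frame %d is not a height x width x 3 array", i),
           call. = FALSE)
    }
    if (roi$x1 > d[2L] || roi$y1 > d[1L]) {
      stop(sprintf("extract_rgb_trace: ROI outside frame bounds at frame %d", i),
           call. = FALSE)
    }
    block <- fr[roi$y0:roi$y1, roi$x0:roi$x1, , drop = FALSE]
    out[i, ] <- apply(block, 3L, mean)
  }
  rgb_trace(out[, 1L], out[, 2L], out[, 3L], sampling_rate)
}

piecewise_detrend <- function(x, w) {
  # least-squares linear fit removed per contiguous segment of w samples;
  # a tail shorter than 2 samples is merged into the preceding segment
  n <- length(x)
  starts <- seq(1L, n, by = w)
  ends <- pmin(starts + w - 1L, n)
  if (length(starts) > 1L && (ends[length(ends)] - starts[length(starts)]) < 1L) {
    ends[length(ends) - 1L] <- n
    starts <- starts[-length(starts)]
    ends <- ends[-length(ends)]
  }
  out <- numeric(n)
  for (k in seq_along(starts)) {
    idx <- starts[k]:ends[k]
    tt <- seq_along(idx)
    fit <- stats::lm.fit(cbind(1, tt), x[idx])
    out[idx] <- fit$residuals
  }
  out
}

#' Detrend and standardize an RGB trace
#'
#' Each channel is linearly detrended over consecutive windows of `window_s`
#' seconds (removing slow illumination drift) and then standardized to zero
#' mean and unit variance, the normalization the source-separation step
#' expects. A channel that is constant after detrending cannot carry pulse
#' information and is zeroed and flagged as degenerate.
#'
#' @param trace an [rgb_trace()].
#' @param window_s detrending window length in seconds (> 0, at most the
#'   trace duration).
#' @return An [rgb_trace()] with an added logical field `degenerate` (named
#'   per channel) and `preprocessed = TRUE`.
#' @export
preprocess_trace <- function(trace, window_s = 30) {
  stopifnot(inherits(trace, "rgb_trace"))
  if (!is.numeric(window_s) || window_s <= 0) {
    stop("preprocess_trace: window_s must be > 0", call. = FALSE)
  }
  n <- length(trace$red)
  fs <- trace$sampling_rate
  w <- round(window_s * fs)
  if (w > n) {
    stop("preprocess_trace: window longer than trace", call. = FALSE)
  }
  w <- max(w, 2L)
  chans <- list(red = trace$red, green = trace$green, blue = trace$blue)
  degenerate <- c(red = FALSE, green = FALSE, blue = FALSE)
  for (nm in names(chans)) {
    d <- piecewise_detrend(chans[[nm]], w)
    s <- stats::sd(d)
    if (!is.finite(s) || s < 1e-12) {
      degenerate[nm] <- TRUE
      chans[[nm]] <- numeric(n)
    } else {
      chans[[nm]] <- (d - mean(d)) / s
    }
  }
  out <- rgb_trace(chans$red, chans$green, chans$blue, fs,
                   timestamps = trace$timestamps)
  out$degenerate <- degenerate
  out$preprocessed <- TRUE
  out
}
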