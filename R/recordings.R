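#' ECG recording container
#'
#' @param samples numeric vector of ECG samples (mV).
#' @param fs sampling rate (Hz), > 0.
#' @param start_time time of the first sample (s).
#' @return An object of class `ecg_recording`.
#' @export
ecg_recording <- function(samples, fs, start_time = 0) {
  check_scalar(fs, "fs", lower = .Machine$double.eps)
  if (!is.numeric(samples) || length(samples) < 2 * fs)
    stopf("ECG recording must hold at least 2 s of samples",
          class = "distractr_invalid_argument")
  structure(list(samples = as.numeric(samples), fs = fs,
                 start_time = start_time),
            class = "ecg_recording")
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("<ecg_recording> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' GSR (skin conductance) recording container
#'
#' @param samples numeric vector of conductance samples (microsiemens).
#' @param fs sampling rate (Hz); wearable GSR units typically stream at 10 Hz.
#' @param start_time time of the first sample (s).
#' @param window_start time of the first stimulus (s); response-window origin.
#' @param window_length response-window length (s), default 300 (5 min).
#' @return An object of class `gsr_recording`.
#' @export
gsr_recording <- function(samples, fs = 10, start_time = 0,
                          window_start = 0, window_length = 300) {
  check_scalar(fs, "fs", lower = .Machine$double.eps)
  check_scalar(window_length, "window_length", lower = .Machine$double.eps)
  structure(list(samples = as.numeric(samples), fs = fs,
                 start_time = start_time, window_start = window_start,
                 window_length = window_length),
            class = "gsr_recording")
}

#' @export
print.gsr_recording <- function(x, ...) {
  cat(sprintf("<gsr_recording> %d samples @ %g Hz, window %g s from %g s\n",
              length(x$samples), x$fs, x$window_length, x$window_start))
  invisible(x)
}

#' Time axis of a recording
#' @param x an `ecg_recording` or `gsr_recording`.
#' @return Numeric vector of sample times (s).
#' @export
rec_time <- function(x) {
  x$start_time + (seq_along(x$samples) - 1L) / x$fs
}

#' Inter-beat interval (RR) series
#'
#' Holds strictly increasing R-peak instants, the successive inter-beat
#' intervals in ms, and per-interval artifact flags.
#'
#' @param peak_times strictly increasing R instants (s); at least 3.
#' @param artifact_flags optional logical vector, one per interval.
#' @return An object of class `rr_series` with elements `peak_times` (s),
#'   `intervals` (ms) and `artifact_flags`.
#' @export
rr_series <- function(peak_times, artifact_flags = NULL) {
  if (length(peak_times) < 3)
    stopf("need at least 3 R peaks to form an RR series",
          class = "distractr_insufficient_data")
  if (any(diff(peak_times) <= 0))
    stopf("R-peak times must be strictly increasing",
          class = "distractr_data_error")
  intervals <- diff(peak_times) * 1000
  if (is.null(artifact_flags)) artifact_flags <- rep(FALSE, length(intervals))
  stopifnot(length(artifact_flags) == length(intervals))
  structure(list(peak_times = as.numeric(peak_times),
                 intervals = as.numeric(intervals),
                 artifact_flags = as.logical(artifact_flags)),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d intervals, mean %.1f ms, %d flagged\n",
              length(x$intervals), mean(x$intervals), sum(x$artifact_flags)))
  invisible(x)
}
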