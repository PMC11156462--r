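#' Band-pass filter an sEMG record
#'
#' Applies a Butterworth band-pass (default 20-450 Hz, the standard sEMG
#' band) forward and backward (zero phase), so that RMS windows downstream
#' are not time-shifted relative to stimulation events.
#'
#' @param record A [semg_signal()].
#' @param low,high Band edges in hertz. `high` must be below the Nyquist
#'   frequency.
#' @param order Butterworth order before the forward-backward doubling.
#' @return A filtered [semg_signal()] of the same length and sampling rate.
#' @examples
#' rec <- semg_signal(rnorm(2000), fs = 1000)
#' filt <- bandpass_filter(rec)
#' @export
bandpass_filter <- function(record, low = 20, high = 450, order = 4) {
  stopifnot(inherits(record, "semg_signal"))
  nyq <- record$fs / 2
  if (!(low > 0 && low < high))
    stop("need 0 < low < high", call. = FALSE)
  if (high >= nyq)
    stop("'high' must be below the Nyquist frequency (", nyq, " Hz)",
         call. = FALSE)
  # effective impulse response of the low edge: ~ order / low seconds
  if (length(record$samples) < 3 * ceiling(order / low * record$fs))
    warning("record is short relative to the filter impulse response; ",
            "edge transients may dominate")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  y <- signal::filtfilt(bf, record$samples)
  out <- record
  out$samples <- as.numeric(y)
  out
}

#' Extract the terminal segment of a record
#'
#' Returns the trailing `window` seconds of the record (for voluntary
#' fatigue trials the final 60 s before task failure are analysed). The
#' returned record re-starts its time axis at zero.
#'
#' @param record A [semg_signal()].
#' @param window Segment length in seconds.
#' @return A [semg_signal()] with exactly `window * fs` samples.
#' @export
extract_terminal_segment <- function(record, window = 60) {
  stopifnot(inherits(record, "semg_signal"))
  n_keep <- round(window * record$fs)
  n <- length(record$samples)
  if (n < n_keep)
    stop("record (", n / record$fs, " s) is shorter than the requested ",
         window, " s segment", call. = FALSE)
  out <- record
  out$samples <- record$samples[(n - n_keep + 1L):n]
  out
}
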