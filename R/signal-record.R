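#' Stimulation protocol
#'
#' Describes one FES pulse train: current amplitude in milliamperes, pulse
#' rate in hertz and pulse width in microseconds. The defaults are the
#' reference protocol used throughout the package (24 Hz, 200 us biphasic
#' pulses; currents between 2 and 15 mA).
#'
#' @param current_mA Current amplitude in milliamperes.
#' @param frequency_Hz Pulse rate in hertz.
#' @param pulse_width_us Pulse width in microseconds.
#' @return An object of class `stim_protocol`.
#' @examples
#' stim_protocol(12)
#' @export
stim_protocol <- function(current_mA = 12, frequency_Hz = 24,
                          pulse_width_us = 200) {
  if (!is.numeric(current_mA) || length(current_mA) != 1L || is.na(current_mA))
    stop("'current_mA' must be a single number", call. = FALSE)
  if (frequency_Hz <= 0) stop("'frequency_Hz' must be positive", call. = FALSE)
  if (pulse_width_us <= 0) stop("'pulse_width_us' must be positive", call. = FALSE)
  structure(
    list(current_mA = as.numeric(current_mA),
         frequency_Hz = as.numeric(frequency_Hz),
         pulse_width_us = as.numeric(pulse_width_us)),
    class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("FES protocol: %g mA, %g Hz, %g us\n",
              x$current_mA, x$frequency_Hz, x$pulse_width_us))
  invisible(x)
}

#' Single-channel sEMG record
#'
#' A uniformly sampled single-channel signal. Sample `i` (0-based) occurs at
#' time `i / fs` seconds. Amplitudes are in arbitrary units.
#'
#' @param samples Numeric vector of amplitude values (non-empty).
#' @param fs Sampling rate in hertz (positive).
#' @param channel Optional channel label.
#' @param protocol Optional [stim_protocol()] for FES trials.
#' @param subject Optional subject identifier.
#' @return An object of class `semg_signal`.
#' @examples
#' semg_signal(sin(2 * pi * 50 * (0:999) / 1000), fs = 1000)
#' @export
semg_signal <- function(samples, fs, channel = "EMG1", protocol = NULL,
                        subject = NULL) {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("'samples' must be a non-empty numeric vector", call. = FALSE)
  if (anyNA(samples)) stop("'samples' must not contain NA", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || is.na(fs) || fs <= 0)
    stop("'fs' must be a single positive number", call. = FALSE)
  if (!is.null(protocol) && !inherits(protocol, "stim_protocol"))
    stop("'protocol' must be a stim_protocol or NULL", call. = FALSE)
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         channel = as.character(channel), protocol = protocol,
         subject = if (is.null(subject)) NULL else as.character(subject)),
    class = "semg_signal")
}

#' @export
print.semg_signal <- function(x, ...) {
  cat(sprintf("sEMG record: %d samples @ %g Hz (%.3f s), channel '%s'\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$channel))
  if (!is.null(x$subject)) cat("  subject:", x$subject, "\n")
  if (!is.null(x$protocol))
    cat(sprintf("  protocol: %g mA, %g Hz, %g us\n", x$protocol$current_mA,
                x$protocol$frequency_Hz, x$protocol$pulse_width_us))
  invisible(x)
}

#' @export
length.semg_signal <- function(x) length(x$samples)

#' Time axis of a record
#'
#' @param record A [semg_signal()].
#' @return Numeric vector of sample times in seconds (0-based).
#' @export
signal_times <- function(record) {
  stopifnot(inherits(record, "semg_signal"))
  (seq_along(record$samples) - 1) / record$fs
}

#' @export
plot.semg_signal <- function(x, ...) {
  graphics::plot(signal_times(x), x$samples, type = "l",
                 xlab = "time (s)", ylab = "amplitude (a.u.)",
                 main = x$channel, ...)
  invisible(x)
}
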