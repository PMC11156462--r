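#' RMS fatigue characteristic curve
#'
#' Window-centre times plus per-window RMS values. Constructed by
#' [windowed_rms()]; users rarely call this directly.
#'
#' @param times Window-centre times in seconds, strictly increasing.
#' @param values Non-negative RMS amplitudes.
#' @param window_samples Window length in samples.
#' @param normalized Logical; `TRUE` after [minmax_normalize()].
#' @param a_min,a_max Extremes of the original curve, recorded when
#'   normalising.
#' @return An object of class `rms_curve`.
#' @export
rms_curve <- function(times, values, window_samples, normalized = FALSE,
                      a_min = NA_real_, a_max = NA_real_) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("'times' and 'values' must have equal length", call. = FALSE)
  if (any(values < 0)) stop("RMS values must be non-negative", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  structure(list(times = times, values = values,
                 window_samples = as.integer(window_samples),
                 normalized = isTRUE(normalized),
                 a_min = a_min, a_max = a_max),
            class = "rms_curve")
}

#' @export
print.rms_curve <- function(x, ...) {
  cat(sprintf("RMS curve: %d windows of %d samples, %s\n", length(x$times),
              x$window_samples,
              if (x$normalized) "normalized to [0, 1]" else "unnormalized"))
  invisible(x)
}

#' @export
as.data.frame.rms_curve <- function(x, ...) {
  data.frame(time_s = x$times, rms = x$values)
}

#' @export
plot.rms_curve <- function(x, ...) {
  graphics::plot(x$times, x$values, xlab = "time (s)",
                 ylab = if (x$normalized) "normalized RMS" else "RMS (a.u.)",
                 ...)
  invisible(x)
}

#' Windowed RMS of an sEMG record
#'
#' Non-overlapping windows of `window_samples` samples (hop equals the
#' window length); per window
#' `RMS = sqrt((x1^2 + ... + xn^2) / n)`. A trailing partial window is
#' discarded. The time assigned to each window is its centre.
#'
#' @param record A [semg_signal()].
#' @param window_samples Window length in samples (default 1000, i.e. 1 s at
#'   a 1 kHz sampling rate).
#' @return An [rms_curve()].
#' @examples
#' rec <- semg_signal(rnorm(5000), fs = 1000)
#' windowed_rms(rec)
#' @export
windowed_rms <- function(record, window_samples = 1000) {
  stopifnot(inherits(record, "semg_signal"))
  w <- as.integer(window_samples)
  if (w < 1L) stop("'window_samples' must be >= 1", call. = FALSE)
  n <- length(record$samples)
  nw <- n %/% w
  if (nw == 0L)
    stop("record (", n, " samples) is shorter than one window (", w,
         " samples)", call. = FALSE)
  x2 <- record$samples[seq_len(nw * w)]^2
  vals <- sqrt(colMeans(matrix(x2, nrow = w)))
  starts <- (seq_len(nw) - 1L) * w                # 0-based start sample
  times <- (starts + (w - 1) / 2) / record$fs     # centre of [start, start+w)
  rms_curve(times, vals, window_samples = w)
}

#' Min-max normalisation of an RMS curve
#'
#' Rescales the curve affinely onto `[0, 1]`:
#' `r' = (r - A_min) / (A_max - A_min)` with `A_min`, `A_max` the curve's
#' extremes, which are recorded on the result. Used to make fatigue
#' characteristic curves comparable across subjects with different absolute
#' muscle strength.
#'
#' @param curve An [rms_curve()] with at least two values and
#'   `max > min`.
#' @return A normalised [rms_curve()] (idempotent on already-normalised
#'   curves that attain both endpoints).
#' @export
minmax_normalize <- function(curve) {
  stopifnot(inherits(curve, "rms_curve"))
  if (length(curve$values) < 2L)
    stop("need at least 2 values to normalize", call. = FALSE)
  a_min <- min(curve$values); a_max <- max(curve$values)
  if (a_max == a_min)
    stop("degenerate curve: max equals min, cannot normalize", call. = FALSE)
  out <- curve
  out$values <- (curve$values - a_min) / (a_max - a_min)
  out$normalized <- TRUE
  out$a_min <- a_min
  out$a_max <- a_max
  out
}
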