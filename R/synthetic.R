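# Synthetic sEMG with planted, recoverable ground truth.
#
# Voluntary trials: band-limited (20-450 Hz) Gaussian carrier, RMS-normalised
# per analysis window, multiplied by a power-law envelope a*t^b + floor, so
# the planted envelope IS the windowed RMS of the output.
#
# FES trials: a biphasic stimulation artifact train plus an evoked component.
# The evoked carrier mixes a phase-continuous tone (the repeatable,
# pulse-locked part of the M-wave train; its gating by the pulse-locked
# burst window produces a slow beat that the scale-128 wavelet extracts)
# with band-limited Gaussian noise (physiological variability), gated after
# each pulse, per-window RMS-normalised, and multiplied by the four-stage
# M-wave envelope.  The stage-3 peak time of the envelope is the planted
# maximum stimulation time.

# evaluate expr with a private RNG stream; global state is untouched
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

.bandlimit <- function(x, fs, low = 20, high = 450) {
  bf <- signal::butter(4, c(low, min(high, 0.95 * fs / 2)) / (fs / 2),
                       type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# per-block RMS normalisation (block = one analysis window)
.block_normalize <- function(x, w) {
  n <- length(x)
  nw <- n %/% w
  for (k in seq_len(nw)) {
    idx <- ((k - 1L) * w + 1L):(k * w)
    r <- sqrt(mean(x[idx]^2))
    if (r > 0) x[idx] <- x[idx] / r
  }
  if (nw * w < n) {
    idx <- (nw * w + 1L):n
    r <- sqrt(mean(x[idx]^2))
    if (r > 0) x[idx] <- x[idx] / r
  }
  x
}

# piecewise half-cosine interpolation: smooth, with critical points exactly
# at the interior knots
.mwave_envelope <- function(t, knots_t, knots_v) {
  v <- numeric(length(t))
  for (s in seq_len(length(knots_t) - 1L)) {
    idx <- t >= knots_t[s] & t <= knots_t[s + 1L]
    if (!any(idx)) next
    ph <- (t[idx] - knots_t[s]) / (knots_t[s + 1L] - knots_t[s])
    v[idx] <- knots_v[s] + (knots_v[s + 1L] - knots_v[s]) *
      (1 - cos(pi * ph)) / 2
  }
  v
}

#' Specification of a synthetic voluntary contraction trial
#'
#' The windowed RMS of the generated signal tracks the planted power-law
#' envelope `envelope_scale * t^envelope_exponent + noise_floor`.
#'
#' @param duration Trial length in seconds (>= 60, so the terminal 60 s
#'   segment exists).
#' @param sampling_rate Hertz.
#' @param envelope_scale Envelope scale `a` (arbitrary amplitude units).
#' @param envelope_exponent Power-law exponent `b` (> 0 for a monotone
#'   growing RMS toward fatigue).
#' @param noise_floor Additive envelope floor, same units as
#'   `envelope_scale`.
#' @param seed Integer seed for the trial's private RNG stream.
#' @return An object of class `voluntary_trial_spec`.
#' @export
voluntary_trial_spec <- function(duration = 90, sampling_rate = 1000,
                                 envelope_scale = 1,
                                 envelope_exponent = 0.6,
                                 noise_floor = 0.05, seed = 1) {
  if (duration < 60)
    stop("invalid spec: duration must be >= 60 s", call. = FALSE)
  if (envelope_exponent <= 0)
    stop("invalid spec: envelope_exponent must be > 0", call. = FALSE)
  if (sampling_rate <= 0)
    stop("invalid spec: sampling_rate must be > 0", call. = FALSE)
  structure(list(duration = duration, sampling_rate = sampling_rate,
                 envelope_scale = envelope_scale,
                 envelope_exponent = envelope_exponent,
                 noise_floor = noise_floor, seed = seed),
            class = "voluntary_trial_spec")
}

#' Generate a synthetic voluntary contraction sEMG record
#'
#' @param spec A [voluntary_trial_spec()].
#' @return A [semg_signal()]; attribute `"planted_envelope"` holds the
#'   envelope evaluated at every sample.
#' @examples
#' rec <- generate_voluntary_semg(voluntary_trial_spec(seed = 42))
#' @export
generate_voluntary_semg <- function(spec) {
  stopifnot(inherits(spec, "voluntary_trial_spec"))
  fs <- spec$sampling_rate
  n <- round(spec$duration * fs)
  w <- round(fs)        # 1-s analysis blocks
  .with_seed(spec$seed, {
    tt <- (0:(n - 1)) / fs
    env <- spec$envelope_scale * tt^spec$envelope_exponent + spec$noise_floor
    if (all(env == 0)) {
      x <- numeric(n)
    } else {
      car <- .block_normalize(.bandlimit(stats::rnorm(n), fs), w)
      x <- car * env
    }
    rec <- semg_signal(x, fs = fs, channel = "voluntary")
    attr(rec, "planted_envelope") <- env
    rec
  })
}

#' Specification of a synthetic FES trial
#'
#' The evoked component's RMS envelope follows the four-stage M-wave shape
#' defined by `stage_durations` (activation, recovery, fatigue, excessive
#' fatigue) and `stage_amplitudes` (first peak, valley, global peak, end
#' level, on top of `base_level`). The planted maximum stimulation time is
#' `sum(stage_durations[1:3])`.
#'
#' @param protocol A [stim_protocol()].
#' @param stage_durations Four positive stage lengths in seconds.
#' @param stage_amplitudes Named or positional vector
#'   `(peak1, valley, peak3, end)`; `peak3` must be the global maximum.
#' @param base_level Envelope value at stimulation onset.
#' @param duration Trial length in seconds; defaults to
#'   `sum(stage_durations)` and must be at least `sum(stage_durations)`.
#' @param sampling_rate Hertz.
#' @param artifact_amplitude Peak amplitude of the biphasic artifact train
#'   (arbitrary units; the evoked global peak is 1 by construction).
#' @param burst_noise_frac Energy fraction of the evoked carrier carried by
#'   band-limited Gaussian noise (the rest is the repeatable pulse-locked
#'   component).
#' @param noise_inband Amplitude of stationary 20-450 Hz background noise.
#' @param noise_broadband Amplitude of white sensor noise.
#' @param seed Integer seed.
#' @return An object of class `fes_trial_spec`.
#' @export
fes_trial_spec <- function(protocol = stim_protocol(),
                           stage_durations = c(5, 7, 28, 15),
                           stage_amplitudes = c(peak1 = 0.6, valley = 0.3,
                                                peak3 = 1.0, end = 0.4),
                           base_level = 0.05,
                           duration = sum(stage_durations),
                           sampling_rate = 1000,
                           artifact_amplitude = 3,
                           burst_noise_frac = 0.2,
                           noise_inband = 0.05,
                           noise_broadband = 0.01,
                           seed = 1) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (length(stage_durations) != 4L || any(stage_durations <= 0))
    stop("invalid spec: need 4 positive stage durations", call. = FALSE)
  if (duration < sum(stage_durations) - 1e-9)
    stop("invalid spec: stage durations must sum to at most the duration",
         call. = FALSE)
  a <- unname(stage_amplitudes)
  if (length(a) != 4L)
    stop("invalid spec: need 4 stage amplitudes", call. = FALSE)
  if (a[3L] < max(a[c(1L, 2L, 4L)], base_level))
    stop("invalid spec: the stage-3 peak must be the global maximum of the envelope",
         call. = FALSE)
  if (burst_noise_frac < 0 || burst_noise_frac > 1)
    stop("invalid spec: burst_noise_frac must lie in [0, 1]", call. = FALSE)
  structure(list(protocol = protocol, stage_durations = stage_durations,
                 stage_amplitudes = a, base_level = base_level,
                 duration = duration, sampling_rate = sampling_rate,
                 artifact_amplitude = artifact_amplitude,
                 burst_noise_frac = burst_noise_frac,
                 noise_inband = noise_inband,
                 noise_broadband = noise_broadband, seed = seed),
            class = "fes_trial_spec")
}

#' Planted peak time of an FES trial spec
#'
#' @param spec A [fes_trial_spec()].
#' @return Seconds from stimulation onset to the planted stage-3 peak.
#' @export
planted_peak_time <- function(spec) {
  stopifnot(inherits(spec, "fes_trial_spec"))
  sum(spec$stage_durations[1:3])
}

# repeatable-component tone: a fixed 2 Hz beat away from a pulse-train
# harmonic, kept inside the 20-450 Hz band
.burst_tone_hz <- function(frequency_Hz) {
  m <- max(1, ceiling(22 / frequency_Hz))
  while (m * frequency_Hz + 2 < 20) m <- m + 1
  min(m * frequency_Hz + 2, 450)
}

#' Generate a synthetic mixed FES sEMG record
#'
#' Output = biphasic artifact train + evoked component + background noise.
#' The ground-truth evoked component is attached as attribute `"evoked"`
#' (a [semg_signal()]), and the planted envelope description as attribute
#' `"planted"` (knot times/values and the stage-3 peak time).
#'
#' @param spec A [fes_trial_spec()].
#' @return A [semg_signal()] carrying the trial protocol.
#' @examples
#' rec <- generate_fes_mixed_signal(fes_trial_spec(seed = 7))
#' ev <- attr(rec, "evoked")
#' @export
generate_fes_mixed_signal <- function(spec) {
  stopifnot(inherits(spec, "fes_trial_spec"))
  fs <- spec$sampling_rate
  fstim <- spec$protocol$frequency_Hz
  if (fstim * spec$duration < 4)
    stop("invalid spec: fewer than 4 stimulation pulses in the trial",
         call. = FALSE)
  n <- round(spec$duration * fs)
  w <- round(fs)
  .with_seed(spec$seed, {
    tt <- (0:(n - 1)) / fs
    d <- spec$stage_durations
    kt <- c(0, d[1L], d[1L] + d[2L], d[1L] + d[2L] + d[3L], spec$duration)
    kv <- c(spec$base_level, spec$stage_amplitudes)
    env <- .mwave_envelope(tt, kt, kv)
    ptimes <- seq(0, spec$duration - 2 / fstim, by = 1 / fstim)
    ps <- round(ptimes * fs)
    ps <- ps[ps < n - 2L]
    # burst gate: 3-18 ms after each pulse
    g0 <- max(1L, round(0.003 * fs)); g1 <- max(g0 + 1L, round(0.018 * fs))
    gate <- numeric(n)
    for (p in ps) gate[(p + g0 + 1L):min(p + g1 + 1L, n)] <- 1
    tone <- sin(2 * pi * .burst_tone_hz(fstim) * tt + 0.7) * gate
    sto <- .bandlimit(stats::rnorm(n), fs) * gate
    unit <- function(x) { r <- sqrt(mean(x^2)); if (r > 0) x / r else x }
    car <- sqrt(1 - spec$burst_noise_frac) * unit(tone) +
      sqrt(spec$burst_noise_frac) * unit(sto)
    if (all(car == 0) || all(env == 0)) {
      ev <- numeric(n)
    } else {
      ev <- .block_normalize(car, w) * env
    }
    # biphasic rectangle, each phase pulse_width/2 wide (>= 1 sample)
    art <- numeric(n)
    hw <- max(1L, round(spec$protocol$pulse_width_us * 1e-6 / 2 * fs))
    if (spec$artifact_amplitude != 0) {
      for (p in ps) {
        art[(p + 1L):min(p + hw, n)] <-
          art[(p + 1L):min(p + hw, n)] + spec$artifact_amplitude
        if (p + hw + 1L <= n)
          art[(p + hw + 1L):min(p + 2L * hw, n)] <-
            art[(p + hw + 1L):min(p + 2L * hw, n)] - spec$artifact_amplitude
      }
    }
    bg <- numeric(n)
    if (spec$noise_broadband > 0)
      bg <- bg + spec$noise_broadband * stats::rnorm(n)
    if (spec$noise_inband > 0)
      bg <- bg + spec$noise_inband * .bandlimit(stats::rnorm(n), fs)
    rec <- semg_signal(ev + art + bg, fs = fs, channel = "fes_mixed",
                       protocol = spec$protocol)
    attr(rec, "evoked") <- semg_signal(ev, fs = fs, channel = "evoked_truth",
                                       protocol = spec$protocol)
    attr(rec, "planted") <- list(knot_times = kt, knot_values = kv,
                                 t_peak = kt[4L])
    rec
  })
}

#' Planted dose-duration ground truth
#'
#' The planted maximum stimulation time at protocol `(I, f, pw)` is
#' `k / (I - i0) + freq_slope * (f - f_ref) + pw_slope * (pw - pw_ref)`:
#' an inverse proportion in current, with linear (signed) corrections for
#' pulse rate and pulse width.
#'
#' @param k Scale of the inverse-proportional law (mA.s), > 0.
#' @param i0 Current offset (mA), >= 0.
#' @param freq_slope Seconds per hertz, <= 0 (raising the pulse rate
#'   shortens the maximum stimulation time).
#' @param pw_slope Seconds per microsecond, >= 0 (widening the pulse
#'   prolongs it).
#' @param reference Reference protocol at which the corrections vanish.
#' @return An object of class `planted_truth`.
#' @export
planted_truth <- function(k = 120, i0 = 0, freq_slope = -0.2,
                          pw_slope = 0.02, reference = stim_protocol()) {
  if (k <= 0) stop("'k' must be > 0", call. = FALSE)
  if (i0 < 0) stop("'i0' must be >= 0", call. = FALSE)
  if (freq_slope > 0) stop("'freq_slope' must be <= 0", call. = FALSE)
  if (pw_slope < 0) stop("'pw_slope' must be >= 0", call. = FALSE)
  structure(list(k = k, i0 = i0, freq_slope = freq_slope,
                 pw_slope = pw_slope, reference = reference),
            class = "planted_truth")
}

#' Planted maximum stimulation time for a protocol
#'
#' @param truth A [planted_truth()].
#' @param protocol A [stim_protocol()]; its current must exceed
#'   `truth$i0`.
#' @return Seconds.
#' @export
planted_t_max <- function(truth, protocol) {
  stopifnot(inherits(truth, "planted_truth"),
            inherits(protocol, "stim_protocol"))
  if (protocol$current_mA <= truth$i0)
    stop("invalid spec: current (", protocol$current_mA,
         " mA) must exceed i0 (", truth$i0, " mA)", call. = FALSE)
  t <- truth$k / (protocol$current_mA - truth$i0) +
    truth$freq_slope * (protocol$frequency_Hz -
                          truth$reference$frequency_Hz) +
    truth$pw_slope * (protocol$pulse_width_us -
                        truth$reference$pulse_width_us)
  if (t <= 1)
    stop("planted peak time ", signif(t, 3),
         " s is too short for an M-wave trial", call. = FALSE)
  t
}

#' Build an FES trial spec whose planted peak follows the ground truth
#'
#' Convenience wrapper: evaluates [planted_t_max()] at the protocol and
#' lays out stage durations so the planted stage-3 peak lands there
#' (activation capped at 5 s, recovery at 7 s, excessive-fatigue tail of
#' at least 10 s).
#'
#' @param truth A [planted_truth()].
#' @param protocol A [stim_protocol()].
#' @param seed Integer seed for the trial.
#' @param noise If `FALSE`, all stochastic components are switched off.
#' @return A [fes_trial_spec()].
#' @export
fes_trial_spec_for <- function(truth, protocol, seed = 1, noise = TRUE) {
  .fes_spec_for_peak(planted_t_max(truth, protocol), protocol, seed,
                     noise = noise)
}

# trial spec whose planted stage-3 peak is at t_peak seconds
.fes_spec_for_peak <- function(t_peak, protocol, seed, noise = TRUE) {
  d1 <- min(0.25 * t_peak, 5)
  d2 <- min(0.30 * t_peak, 7)
  d3 <- t_peak - d1 - d2
  d4 <- max(0.35 * t_peak, 10)
  fes_trial_spec(protocol = protocol,
                 stage_durations = c(d1, d2, d3, d4),
                 seed = seed,
                 burst_noise_frac = if (noise) 0.2 else 0,
                 noise_inband = if (noise) 0.05 else 0,
                 noise_broadband = if (noise) 0.01 else 0)
}

#' Generate a synthetic FES cohort with planted dose-duration ground truth
#'
#' One trial per subject and current. Each subject carries a single
#' multiplicative log-normal jitter factor applied to the planted peak
#' times (peak times are positive, hence the log-normal choice); with
#' `jitter_sd = 0` the planted map current -> peak time is exactly
#' `k / (I - i0)`.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param currents Currents in milliamperes, all above `truth$i0`.
#' @param truth A [planted_truth()].
#' @param seed Integer master seed; per-trial seeds are derived from it.
#' @param jitter_sd Standard deviation of the subjects' log-normal jitter.
#' @param noise If `FALSE`, all stochastic components of the trials
#'   (carrier noise fraction and background noise) are switched off.
#' @param generate If `FALSE`, only specs and the ground-truth table are
#'   returned (no signal synthesis).
#' @return A list of class `fes_cohort`: `trials` (each with `subject`,
#'   `spec` and, when generated, `record`) and `truth` (a data frame
#'   `subject, current_mA, frequency_Hz, pulse_width_us, planted_t_max_s,
#'   seed`).
#' @export
generate_cohort <- function(n_subjects, currents, truth = planted_truth(),
                            seed = 1, jitter_sd = 0.05, noise = TRUE,
                            generate = TRUE) {
  if (n_subjects < 1) stop("invalid spec: n_subjects must be >= 1",
                           call. = FALSE)
  if (any(currents <= truth$i0))
    stop("invalid spec: all currents must exceed i0 = ", truth$i0,
         call. = FALSE)
  jit <- .with_seed(seed, exp(stats::rnorm(n_subjects, 0, jitter_sd)))
  trials <- list()
  rows <- list()
  for (s in seq_len(n_subjects)) {
    for (ci in seq_along(currents)) {
      proto <- stim_protocol(current_mA = currents[ci],
                             frequency_Hz = truth$reference$frequency_Hz,
                             pulse_width_us = truth$reference$pulse_width_us)
      tp <- planted_t_max(truth, proto) * jit[s]
      trial_seed <- (seed + 7919L * s + 104729L * ci) %% .Machine$integer.max
      spec <- .fes_spec_for_peak(tp, proto, trial_seed, noise = noise)
      rec <- if (generate) generate_fes_mixed_signal(spec) else NULL
      if (!is.null(rec)) rec$subject <- sprintf("S%02d", s)
      trials[[length(trials) + 1L]] <-
        list(subject = sprintf("S%02d", s), spec = spec, record = rec)
      rows[[length(rows) + 1L]] <-
        data.frame(subject = sprintf("S%02d", s),
                   current_mA = currents[ci],
                   frequency_Hz = proto$frequency_Hz,
                   pulse_width_us = proto$pulse_width_us,
                   planted_t_max_s = tp, seed = trial_seed)
    }
  }
  structure(list(trials = trials, truth = do.call(rbind, rows)),
            class = "fes_cohort")
}

#' @export
print.fes_cohort <- function(x, ...) {
  cat(sprintf("Synthetic FES cohort: %d trials, %d subjects, currents %s mA\n",
              length(x$trials), length(unique(x$truth$subject)),
              paste(range(x$truth$current_mA), collapse = "-")))
  invisible(x)
}
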