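# Independent oracles used across the suite.  Each is a deliberately
# naive, direct evaluation of the defining formula, kept free of the code
# paths it checks.

# dense (full-support, O(n^2)) evaluation of the single-scale wavelet
# transform: WT(a, m) = (1/sqrt(a)) * sum_i x[i] psi((i - m)/a) / fs
oracle_cwt <- function(x, a, fs, psi = mexican_hat) {
  n <- length(x)
  idx <- seq_len(n) - 1
  vapply(idx, function(m) sum(x * psi((idx - m) / a)) / sqrt(a) / fs, 0)
}

# direct evaluation of RMS = sqrt((x1^2 + ... + xn^2)/n) per window
oracle_windowed_rms <- function(x, w) {
  nw <- length(x) %/% w
  vapply(seq_len(nw), function(k) {
    xs <- x[((k - 1) * w + 1):(k * w)]
    sqrt(sum(xs^2) / w)
  }, 0)
}

# closed-form log-log regression for y = a * t^b
oracle_loglog_power <- function(t, y) {
  lx <- log(t); ly <- log(y)
  b <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  a <- exp(mean(ly) - b * mean(lx))
  c(a = a, b = b)
}

# amplitude gain of the forward-backward Butterworth band-pass at f Hz,
# from the designed coefficients evaluated on the unit circle
oracle_filtfilt_gain <- function(f, fs, low = 20, high = 450, order = 4) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  z <- exp(-1i * 2 * pi * f / fs)
  H <- sum(bf$b * z^(seq_along(bf$b) - 1)) /
    sum(bf$a * z^(seq_along(bf$a) - 1))
  Mod(H)^2                       # applied forward and backward
}

# brute-force fine-grid local extrema of a fitted curve on [t0, t1]
oracle_grid_extrema <- function(fit, t0, t1, step = 0.01) {
  tt <- seq(t0, t1, by = step)
  y <- predict(fit, tt)
  d <- diff(y)
  idx <- which(d[-1] * d[-length(d)] < 0) + 1
  list(times = tt[idx], values = y[idx], maxima = d[idx - 1] > 0)
}

# amplitude of a sinusoidal component over the central half of a record
central_amplitude <- function(x) {
  n <- length(x)
  mid <- x[floor(n / 4):ceiling(3 * n / 4)]
  sqrt(2 * mean(mid^2))
}

# canonical clean M-wave RMS curve: four-stage envelope sampled at the
# analysis-window centres
mwave_fixture_curve <- function(knot_t = c(0, 5, 12, 40, 55),
                                knot_v = c(0.05, 0.6, 0.3, 1.0, 0.4),
                                fs = 1000, w = 1000) {
  nw <- floor(knot_t[length(knot_t)] * fs / w)
  centres <- ((seq_len(nw) - 1) * w + (w - 1) / 2) / fs
  env <- fesfatigue:::.mwave_envelope(centres, knot_t, knot_v)
  rms_curve(centres, env, window_samples = w)
}

band_energy <- function(x, fs, f_lo, f_hi) {
  sp <- Mod(stats::fft(x))^2
  fr <- (seq_along(x) - 1) / length(x) * fs
  sum(sp[fr >= f_lo & fr <= f_hi & fr <= fs / 2])
}
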