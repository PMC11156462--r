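# Four-stage decomposition of the FES-evoked fatigue characteristic curve
# ("M"-wave): (1) activation -- rest to active, up to the first local
# maximum; (2) recovery -- settling to the local minimum; (3) fatigue --
# rise to the global maximum, whose time is the maximum stimulation time;
# (4) excessive fatigue -- decline beyond it.  Stage boundaries are
# critical points of the FITTED polynomial (raw RMS curves are too noisy
# for extrema placement).

.mwave_labels <- c("activation", "recovery", "fatigue", "excessive_fatigue")

.shape_error <- function(msg, critical_points) {
  stop(structure(
    list(message = paste0(msg, " (critical points found: ",
                          if (length(critical_points))
                            paste(signif(critical_points, 4),
                                  collapse = ", ")
                          else "none", ")"),
         call = NULL, critical_points = critical_points),
    class = c("fesfatigue_shape_error", "error", "condition")))
}

#' Segment an FES fatigue curve into the four M-wave stages
#'
#' Places the three interior stage boundaries at, in order: the first local
#' maximum of the fitted polynomial (end of activation), the subsequent
#' local minimum (end of recovery) and the global maximum (end of the
#' fatigue stage, onset of excessive fatigue). The global-maximum time is
#' the maximum stimulation time. Ties between equal-height maxima are
#' broken toward the earlier time (the shorter, conservative stimulation
#' duration).
#'
#' @param fit A polynomial [fatigue_fit] of the curve.
#' @param curve The normalised [rms_curve()] that was fitted.
#' @return An object of class `mwave_stages` with elements `boundaries`
#'   (three interior times, seconds), `labels`, `stages` (a data frame of
#'   labelled intervals), `t_max` and `peak_value`.
#' @export
segment_mwave_stages <- function(fit, curve) {
  stopifnot(inherits(fit, "fatigue_fit"), inherits(curve, "rms_curve"))
  if (fit$family != "polynomial")
    stop("segmentation requires a polynomial fit", call. = FALSE)
  if (!curve$normalized)
    stop("segmentation requires a normalized curve", call. = FALSE)
  sc <- fit$scaled
  d <- fit$degree
  t0 <- min(curve$times); t1 <- max(curve$times)
  s0 <- (t0 - sc$mu) / sc$sd; s1 <- (t1 - sc$mu) / sc$sd
  dco <- sc$coef[-1L] * seq_len(d)
  # strip numerically null leading-order terms before root finding
  tol <- 1e-12 * max(abs(dco))
  while (length(dco) > 1L && abs(dco[length(dco)]) < tol)
    dco <- dco[-length(dco)]
  if (length(dco) < 2L)
    .shape_error("curve is not M-shaped: fewer than 3 interior critical points",
                 numeric(0))
  rts <- polyroot(dco)
  crit_s <- sort(Re(rts)[abs(Im(rts)) < 1e-7 * max(1, abs(Re(rts)))])
  crit_s <- crit_s[crit_s > s0 & crit_s < s1]
  crit_t <- crit_s * sc$sd + sc$mu
  if (length(crit_s) < 3L)
    .shape_error("curve is not M-shaped: fewer than 3 interior critical points",
                 crit_t)
  # classify by the sign change of the first derivative around each root
  eps <- (s1 - s0) * 1e-6
  d1 <- function(z) sum(dco * z^(0:(d - 1L)))
  is_max <- vapply(crit_s, function(z) d1(z - eps) > 0 && d1(z + eps) < 0,
                   NA)
  is_min <- vapply(crit_s, function(z) d1(z - eps) < 0 && d1(z + eps) > 0,
                   NA)
  i1 <- which(is_max)[1L]
  if (is.na(i1))
    .shape_error("curve is not M-shaped: no interior local maximum", crit_t)
  i2 <- which(is_min & seq_along(crit_s) > i1)[1L]
  if (is.na(i2))
    .shape_error("curve is not M-shaped: no local minimum after the first peak",
                 crit_t)
  cand <- which(is_max & seq_along(crit_s) > i2)
  if (!length(cand))
    .shape_error("curve is not M-shaped: no fatigue-stage peak after the recovery minimum",
                 crit_t)
  vals <- .poly_eval(sc$coef, crit_s[cand])
  i3 <- cand[which.max(vals)]          # which.max breaks ties toward earlier
  b <- crit_t[c(i1, i2, i3)]
  if (any(diff(b) <= 0))
    .shape_error("degenerate stage boundaries", crit_t)
  stages <- data.frame(stage = 1:4, label = .mwave_labels,
                       start_s = c(t0, b), end_s = c(b, t1))
  structure(list(boundaries = b, labels = .mwave_labels, stages = stages,
                 t_max = b[3L],
                 peak_value = .poly_eval(sc$coef, crit_s[i3]),
                 critical_points = crit_t),
            class = "mwave_stages")
}

#' @export
print.mwave_stages <- function(x, ...) {
  cat("M-wave segmentation (4 stages)\n")
  print(transform(x$stages, start_s = signif(start_s, 4),
                  end_s = signif(end_s, 4)), row.names = FALSE)
  cat(sprintf("maximum stimulation time: %.3f s (peak %.3f)\n",
              x$t_max, x$peak_value))
  invisible(x)
}

#' @export
plot.mwave_stages <- function(x, fit = NULL, ...) {
  st <- x$stages
  graphics::plot(NA, xlim = range(c(st$start_s, st$end_s)), ylim = c(0, 1.05),
                 xlab = "time (s)", ylab = "normalized iRMS", ...)
  cols <- grDevices::adjustcolor(c("skyblue", "palegreen", "orange", "salmon"),
                                 0.4)
  for (i in 1:4)
    graphics::rect(st$start_s[i], 0, st$end_s[i], 1.05, col = cols[i],
                   border = NA)
  if (!is.null(fit)) {
    tt <- seq(min(fit$times), max(fit$times), length.out = 400)
    graphics::lines(tt, predict(fit, tt), lwd = 2)
    graphics::points(fit$times, fit$values, pch = 20, col = "grey30")
  }
  graphics::abline(v = x$t_max, lty = 2)
  invisible(x)
}

#' Maximum stimulation time of a segmented FES response
#'
#' The time from stimulation onset to the global maximum of the fatigue
#' (third) stage: the safe stimulation duration at the trial's current.
#'
#' @param seg An `mwave_stages` object from [segment_mwave_stages()].
#' @return Time in seconds.
#' @export
max_stimulation_time <- function(seg) {
  stopifnot(inherits(seg, "mwave_stages"))
  seg$t_max
}
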