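# Dose-duration model: the maximum stimulation time falls off with current
# amplitude as an inverse proportion,
#
#     t(I) = k / (I - i0),        k > 0,  0 <= i0 < min(I),
#
# where k (mA.s) scales the trade-off and i0 (mA) is a rheobase-like
# offset; i0 = 0 recovers the strict inverse proportion.

#' Fit the inverse-proportional current-time relationship
#'
#' Nonlinear least squares for `t = k / (I - i0)` with `i0` constrained to
#' `[0, 0.95 * min(I))`. If the two-parameter fit fails to converge, the
#' one-parameter model with `i0 = 0` is used (closed form
#' `k = sum(t/I) / sum(1/I^2)`), and the result is flagged.
#'
#' @param current Currents in milliamperes (at least 3 distinct values), or
#'   a two-column data frame `(current, t_max)`.
#' @param t_max Maximum stimulation times in seconds, all positive.
#' @return An object of class `fes_time_fit` with elements `k`, `i0`,
#'   `residuals`, `r_squared`, `p_value`, `fallback`.
#' @examples
#' I <- 2:15
#' fit <- fit_current_time_relationship(I, 120 / I)
#' coef(fit)
#' @export
fit_current_time_relationship <- function(current, t_max = NULL) {
  if (is.data.frame(current)) {
    t_max <- current[[2L]]
    current <- current[[1L]]
  }
  if (length(current) != length(t_max))
    stop("'current' and 't_max' must have equal length", call. = FALSE)
  keep <- !(is.na(current) | is.na(t_max))
  current <- current[keep]; t_max <- t_max[keep]
  if (length(unique(current)) < 3L)
    stop("need at least 3 distinct currents", call. = FALSE)
  if (any(t_max <= 0)) stop("all t_max must be positive", call. = FALSE)
  rho <- suppressWarnings(stats::cor(current, t_max, method = "spearman"))
  if (!is.na(rho) && rho >= 0)
    warning("t_max does not decrease with current (rank correlation >= 0)")
  dat <- data.frame(I = current, t = t_max)
  k0 <- sum(t_max / current) / sum(1 / current^2)   # closed form, i0 = 0
  fit <- tryCatch(
    stats::nls(t ~ k / (I - i0), data = dat,
               start = list(k = k0, i0 = min(current) * 0.01),
               algorithm = "port",
               lower = c(k = 1e-12, i0 = 0),
               upper = c(k = Inf, i0 = 0.95 * min(current)),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    k <- unname(stats::coef(fit)[["k"]])
    i0 <- unname(stats::coef(fit)[["i0"]])
    fallback <- FALSE
  } else {
    k <- k0; i0 <- 0; fallback <- TRUE
  }
  pred <- k / (current - i0)
  res <- t_max - pred
  sst <- sum((t_max - mean(t_max))^2)
  ssr <- sum(res^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
  n <- length(t_max); npar <- if (fallback) 1L else 2L
  p <- if (sst > 0 && n > npar && ssr > 0) {
    f <- ((sst - ssr) / (npar)) / (ssr / (n - npar - 1L))
    stats::pf(f, npar, n - npar - 1L, lower.tail = FALSE)
  } else if (sst > 0 && ssr == 0) 0 else NA_real_
  structure(list(k = k, i0 = i0, residuals = res, fitted_values = pred,
                 current = current, t_max = t_max,
                 r_squared = r2, p_value = p, fallback = fallback),
            class = "fes_time_fit")
}

#' @export
coef.fes_time_fit <- function(object, ...) c(k = object$k, i0 = object$i0)

#' @export
predict.fes_time_fit <- function(object, current = NULL, ...) {
  if (is.null(current)) return(object$fitted_values)
  if (any(current <= object$i0))
    stop("currents must exceed the fitted offset i0 = ", object$i0,
         call. = FALSE)
  object$k / (current - object$i0)
}

#' @export
residuals.fes_time_fit <- function(object, ...) object$residuals

#' @export
print.fes_time_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Inverse-proportional dose-duration fit: t(I) = %.*g / (I - %.*g)\n",
              digits, x$k, digits, x$i0))
  cat(sprintf("  n = %d, R^2 = %.*g, p = %.*g%s\n", length(x$t_max), digits,
              x$r_squared, digits, x$p_value,
              if (x$fallback) " [one-parameter fallback, i0 = 0]" else ""))
  invisible(x)
}

#' @export
summary.fes_time_fit <- function(object, ...) {
  print(object)
  cat("per-point residuals (s):\n")
  print(data.frame(current_mA = object$current, t_max_s = object$t_max,
                   fitted_s = signif(object$fitted_values, 5),
                   residual_s = signif(object$residuals, 5)),
        row.names = FALSE)
  invisible(object)
}

#' @export
plot.fes_time_fit <- function(x, ...) {
  graphics::plot(x$current, x$t_max, xlab = "current (mA)",
                 ylab = "maximum stimulation time (s)", ...)
  ii <- seq(min(x$current), max(x$current), length.out = 200)
  graphics::lines(ii, predict(x, ii), col = "red", lwd = 2)
  invisible(x)
}

#' Compare two dose-duration fits over a current range
#'
#' Reports the maximum and mean absolute difference of the predicted
#' maximum stimulation time over the supplied currents, and the relative
#' difference of `k` -- used to cross-validate an experimental-group fit
#' against a test-group fit.
#'
#' @param fit_a,fit_b `fes_time_fit` objects.
#' @param currents Currents (mA) at which to compare; each must exceed both
#'   fitted offsets.
#' @return A list with `max_abs_diff_s`, `mean_abs_diff_s`,
#'   `rel_k_diff` (`|k_a - k_b|` relative to the smaller `k`) and the
#'   per-current predictions.
#' @export
crossvalidate_relationship <- function(fit_a, fit_b, currents) {
  stopifnot(inherits(fit_a, "fes_time_fit"), inherits(fit_b, "fes_time_fit"))
  if (any(currents <= max(fit_a$i0, fit_b$i0)))
    stop("all currents must exceed both fitted offsets (max i0 = ",
         max(fit_a$i0, fit_b$i0), ")", call. = FALSE)
  pa <- predict(fit_a, currents)
  pb <- predict(fit_b, currents)
  list(max_abs_diff_s = max(abs(pa - pb)),
       mean_abs_diff_s = mean(abs(pa - pb)),
       rel_k_diff = abs(fit_a$k - fit_b$k) / min(fit_a$k, fit_b$k),
       currents = currents, pred_a = pa, pred_b = pb)
}

#' Trend of the maximum stimulation time in each FES parameter
#'
#' Given trials in which exactly one protocol field at a time is varied
#' around a reference protocol, reports the sign of the monotone trend
#' (Spearman rank correlation) of `t_max` against each varied field.
#' Expected physiology: current `-`, frequency `-`, pulse width `+`.
#'
#' @param trials A data frame with columns `current_mA`, `frequency_Hz`,
#'   `pulse_width_us`, `t_max_s` (one row per trial).
#' @param reference The reference protocol (a [stim_protocol()]); trials
#'   differing from it in more than one field are a confounded design and
#'   raise an error.
#' @return A data frame with one row per protocol field: the number of
#'   trials, Spearman rho, and the trend sign (`"-"`, `"+"`, or
#'   `"undefined"` when fewer than two distinct levels are present).
#' @export
parameter_effect_summary <- function(trials, reference = stim_protocol()) {
  stopifnot(is.data.frame(trials))
  need <- c("current_mA", "frequency_Hz", "pulse_width_us", "t_max_s")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  ref <- c(current_mA = reference$current_mA,
           frequency_Hz = reference$frequency_Hz,
           pulse_width_us = reference$pulse_width_us)
  fields <- names(ref)
  devmat <- vapply(fields, function(f) trials[[f]] != ref[[f]],
                   logical(nrow(trials)))
  if (!is.matrix(devmat))
    devmat <- matrix(devmat, nrow = nrow(trials),
                     dimnames = list(NULL, fields))
  nvary <- rowSums(devmat)
  if (any(nvary > 1L))
    stop("confounded design: trial(s) ",
         paste(which(nvary > 1L), collapse = ", "),
         " vary more than one protocol field from the reference",
         call. = FALSE)
  out <- lapply(fields, function(f) {
    idx <- nvary == 0L | devmat[, f]      # reference trials anchor each group
    x <- trials[[f]][idx]; y <- trials$t_max_s[idx]
    if (length(unique(x)) < 2L)
      return(data.frame(field = f, n = sum(idx), rho = NA_real_,
                        sign = "undefined"))
    rho <- stats::cor(x, y, method = "spearman")
    data.frame(field = f, n = sum(idx), rho = rho,
               sign = if (rho < 0) "-" else if (rho > 0) "+" else "0")
  })
  do.call(rbind, out)
}
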