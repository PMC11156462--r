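# Curve fitting of RMS fatigue characteristic curves.  Voluntary trials are
# fitted by a power function y = a * t^b (solved in log-log space: closed
# form, deterministic); FES-evoked curves by an ordinary least-squares
# polynomial.  The fitted values are the fatigue index curve (iRMS).

#' Fitted fatigue characteristic curve
#'
#' Returned by [fit_power_curve()] and [fit_polynomial_curve()]. Supports
#' `print`, `summary`, `coef`, `predict`, `fitted`, `residuals` and `plot`.
#'
#' @name fatigue_fit
#' @seealso [fit_power_curve()], [fit_polynomial_curve()]
NULL

.new_fatigue_fit <- function(family, coefficients, curve, fitted_values,
                             r_squared, p_value, degree = NA_integer_,
                             scaled = NULL) {
  structure(list(family = family, coefficients = coefficients,
                 degree = degree, r_squared = r_squared, p_value = p_value,
                 times = curve$times, values = curve$values,
                 fitted_values = fitted_values, scaled = scaled),
            class = "fatigue_fit")
}

#' Fit a power function to an RMS curve
#'
#' Least-squares fit of `value = a * time^b`, solved in log-log space
#' (ordinary linear regression of `log(value)` on `log(time)`), which is
#' deterministic and has a closed form. Values at or below zero are floored
#' at machine epsilon before the log, with a warning.
#'
#' @param curve An [rms_curve()] with all times positive and at least 3
#'   points.
#' @return A [fatigue_fit] with `coefficients = c(a, b)`. `r_squared` is
#'   computed on the original scale; `p_value` is the overall F-test
#'   significance of the log-log regression.
#' @examples
#' cv <- rms_curve(1:20, 2 * (1:20)^0.5, window_samples = 1000)
#' coef(fit_power_curve(cv))
#' @export
fit_power_curve <- function(curve) {
  stopifnot(inherits(curve, "rms_curve"))
  if (any(curve$times <= 0))
    stop("power fit requires all times > 0", call. = FALSE)
  if (length(curve$times) < 3L)
    stop("power fit requires at least 3 points", call. = FALSE)
  y <- curve$values
  if (any(y <= 0)) {
    warning("flooring ", sum(y <= 0), " non-positive RMS value(s) at ",
            "machine epsilon before the log transform")
    y <- pmax(y, .Machine$double.eps)
  }
  fit <- stats::lm(log(y) ~ log(curve$times))
  b <- unname(stats::coef(fit)[2L])
  a <- exp(unname(stats::coef(fit)[1L]))
  yhat <- a * curve$times^b
  sst <- sum((curve$values - mean(curve$values))^2)
  r2 <- if (sst > 0) 1 - sum((curve$values - yhat)^2) / sst else NA_real_
  fs <- suppressWarnings(summary(fit))$fstatistic
  p <- if (!is.null(fs) && is.finite(fs[1L]))
    unname(stats::pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE))
  else NA_real_
  .new_fatigue_fit("power", c(a = a, b = b), curve, yhat, r2, p)
}

#' Fit a polynomial to an RMS curve
#'
#' Ordinary least-squares polynomial fit. The default degree 6 is the
#' smallest with comfortable slack for the four-stage M-wave shape, which
#' has three interior critical points (degree >= 4 is the hard minimum).
#' The fit is computed on a centred and scaled time axis for conditioning;
#' `coefficients` are reported in the raw time basis.
#'
#' @param curve An [rms_curve()].
#' @param degree Polynomial degree; must satisfy
#'   `length(curve$values) > degree + 1`.
#' @return A [fatigue_fit] with `degree` and polynomial `coefficients`
#'   (constant term first).
#' @export
fit_polynomial_curve <- function(curve, degree = 6) {
  stopifnot(inherits(curve, "rms_curve"))
  degree <- as.integer(degree)
  if (degree < 0L) stop("'degree' must be >= 0", call. = FALSE)
  npt <- length(curve$values)
  if (npt <= degree + 1L)
    stop("underdetermined: ", npt, " points for degree ", degree,
         " (need more than degree + 1)", call. = FALSE)
  mu <- mean(curve$times)
  sdv <- if (npt > 1L) stats::sd(curve$times) else 1
  if (sdv == 0) sdv <- 1
  s <- (curve$times - mu) / sdv
  X <- outer(s, 0:degree, `^`)
  qrX <- qr(X)
  cs <- qr.coef(qrX, curve$values)
  yhat <- drop(X %*% cs)
  ssr <- sum((curve$values - yhat)^2)
  sst <- sum((curve$values - mean(curve$values))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
  p <- if (degree >= 1L && sst > 0 && npt > degree + 1L) {
    f <- ((sst - ssr) / degree) / (ssr / (npt - degree - 1L))
    stats::pf(f, degree, npt - degree - 1L, lower.tail = FALSE)
  } else NA_real_
  .new_fatigue_fit("polynomial", .scaled_to_raw(cs, mu, sdv), curve, yhat,
                   r2, p, degree = degree,
                   scaled = list(coef = cs, mu = mu, sd = sdv))
}

# expand sum_k c_k ((t - mu)/sd)^k into raw powers of t
.scaled_to_raw <- function(cs, mu, sdv) {
  d <- length(cs) - 1L
  raw <- numeric(d + 1L)
  for (k in 0:d) {
    ck <- cs[k + 1L] / sdv^k
    for (i in 0:k)
      raw[i + 1L] <- raw[i + 1L] + ck * choose(k, i) * (-mu)^(k - i)
  }
  names(raw) <- paste0("t^", 0:d)
  raw
}

# evaluate polynomial (scaled basis) and derivatives
.poly_eval <- function(cs, s) {
  d <- length(cs) - 1L
  vapply(s, function(z) sum(cs * z^(0:d)), 0)
}

#' @export
predict.fatigue_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) return(object$fitted_values)
  if (object$family == "power") {
    object$coefficients[["a"]] * times^object$coefficients[["b"]]
  } else {
    sc <- object$scaled
    .poly_eval(sc$coef, (times - sc$mu) / sc$sd)
  }
}

#' @export
fitted.fatigue_fit <- function(object, ...) object$fitted_values

#' @export
residuals.fatigue_fit <- function(object, ...) {
  object$values - object$fitted_values
}

#' @export
coef.fatigue_fit <- function(object, ...) object$coefficients

#' @export
print.fatigue_fit <- function(x, digits = 4, ...) {
  if (x$family == "power") {
    cat(sprintf("Power fit: iRMS(t) = %.*g * t^%.*g\n", digits,
                x$coefficients[["a"]], digits, x$coefficients[["b"]]))
  } else {
    cat(sprintf("Polynomial fit (degree %d)\n", x$degree))
  }
  cat(sprintf("  R^2 = %.*g, p = %.*g, n = %d\n", digits, x$r_squared,
              digits, x$p_value, length(x$times)))
  invisible(x)
}

#' @export
summary.fatigue_fit <- function(object, ...) {
  print(object)
  cat("coefficients:\n")
  print(object$coefficients)
  cat(sprintf("residual sd: %g\n", stats::sd(residuals(object))))
  invisible(object)
}

#' @export
plot.fatigue_fit <- function(x, ...) {
  graphics::plot(x$times, x$values, xlab = "time (s)", ylab = "RMS",
                 col = "grey40", ...)
  graphics::lines(x$times, x$fitted_values, col = "red", lwd = 2)
  invisible(x)
}
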