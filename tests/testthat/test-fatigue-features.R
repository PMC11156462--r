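test_that("windowed RMS evaluates the defining formula", {
  expect_equal(windowed_rms(semg_signal(c(3, 4), 10), 2)$values,
               sqrt(12.5))
  rec <- semg_signal(rep(-2.5, 3000), 1000)
  expect_equal(windowed_rms(rec)$values, rep(2.5, 3))
  set.seed(8)
  x <- rnorm(5300)
  cv <- windowed_rms(semg_signal(x, 1000), 500)
  expect_equal(cv$values, oracle_windowed_rms(x, 500))
})

test_that("windows are non-overlapping, centred, trailing partials dropped", {
  cv <- windowed_rms(semg_signal(rnorm(2500), 1000), 1000)
  expect_length(cv$values, 2L)
  expect_equal(cv$times, (c(0, 1000) + 999 / 2) / 1000)
  expect_error(windowed_rms(semg_signal(rnorm(500), 1000), 1000),
               "shorter than one window")
})

test_that("RMS is scale-equivariant", {
  set.seed(9)
  x <- rnorm(4000)
  base <- windowed_rms(semg_signal(x, 1000))$values
  for (alpha in c(0.01, -3, 250)) {
    expect_equal(windowed_rms(semg_signal(alpha * x, 1000))$values,
                 abs(alpha) * base)
  }
})

test_that("min-max normalisation maps onto [0, 1] and is idempotent", {
  cv <- rms_curve(1:3, c(2, 4, 6), 1000)
  nm <- minmax_normalize(cv)
  expect_equal(nm$values, c(0, 0.5, 1))
  expect_true(nm$normalized)
  expect_equal(nm$a_min, 2); expect_equal(nm$a_max, 6)
  expect_equal(minmax_normalize(nm)$values, nm$values)
  expect_error(minmax_normalize(rms_curve(1:3, rep(2, 3), 1000)),
               "degenerate")
})

test_that("normalisation is invariant to positive affine input transforms", {
  set.seed(10)
  for (rep in 1:10) {
    y <- runif(30, 1, 5)
    base <- minmax_normalize(rms_curve(1:30, y, 1000))$values
    a <- runif(1, 0.1, 10); b <- runif(1, 0, 100)
    tr <- minmax_normalize(rms_curve(1:30, a * y + b, 1000))$values
    expect_equal(tr, base, tolerance = 1e-12)
  }
})

test_that("power fit recovers exact power laws and matches the oracle", {
  tt <- 1:60
  fit <- fit_power_curve(rms_curve(tt, 2 * tt^0.5, 1000))
  expect_equal(unname(coef(fit)), c(2, 0.5), tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  set.seed(12)
  y <- exp(0.3 + 0.7 * log(tt) + rnorm(60, 0, 0.1))
  fit2 <- fit_power_curve(rms_curve(tt, y, 1000))
  expect_equal(unname(coef(fit2)), unname(oracle_loglog_power(tt, y)),
               tolerance = 1e-6)

  cst <- fit_power_curve(rms_curve(tt, rep(5, 60), 1000))
  expect_lt(abs(coef(cst)[["b"]]), 1e-6)
  expect_equal(coef(cst)[["a"]], 5, tolerance = 1e-9)

  expect_error(fit_power_curve(rms_curve(0:10, 1:11, 1000)), "times > 0")
  expect_error(fit_power_curve(rms_curve(1:2, 1:2, 1000)), "3 points")
  expect_warning(fit_power_curve(rms_curve(1:10, c(0, 2:10), 1000)),
                 "flooring")
})

test_that("power-law exponent is recovered under multiplicative noise", {
  set.seed(13)
  tt <- 1:60
  hit <- vapply(1:200, function(i) {
    y <- tt^0.8 * (1 + rnorm(60, 0, 0.05))
    abs(coef(fit_power_curve(rms_curve(tt, pmax(y, 1e-12), 1000)))[["b"]] -
          0.8) <= 0.1
  }, NA)
  expect_gte(mean(hit), 0.95)
})

test_that("polynomial fit interpolates its own family and reports fit stats", {
  tt <- seq(1, 20, by = 0.5)
  cubic <- function(t) 5 + 0.5 * t - 0.04 * t^2 + 0.001 * t^3
  fit <- fit_polynomial_curve(rms_curve(tt, cubic(tt), 1000), degree = 3)
  expect_lt(max(abs(residuals(fit))), 1e-9)
  expect_equal(predict(fit, c(2.25, 7.75)), cubic(c(2.25, 7.75)),
               tolerance = 1e-9)
  # raw-basis coefficients agree with direct evaluation
  raw <- coef(fit)
  expect_equal(sum(raw * 5^(0:3)), unname(predict(fit, 5)),
               tolerance = 1e-8)

  flat <- fit_polynomial_curve(rms_curve(1:10, runif(10), 1000), degree = 0)
  expect_equal(unique(round(flat$fitted_values, 12)),
               round(mean(flat$values), 12))

  expect_error(fit_polynomial_curve(rms_curve(1:7, 1:7, 1000), degree = 6),
               "underdetermined")
})

test_that("degree-6 polynomial captures the canonical M-wave envelope", {
  cv <- minmax_normalize(mwave_fixture_curve())
  fit <- fit_polynomial_curve(cv, degree = 6)
  expect_gt(fit$r_squared, 0.9)
  expect_lt(fit$p_value, 0.05)
})
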