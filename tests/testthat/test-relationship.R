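test_that("noiseless inverse-proportional data are recovered exactly", {
  I <- 2:15
  fit <- fit_current_time_relationship(I, 120 / I)
  expect_equal(fit$k, 120, tolerance = 1e-6)
  expect_equal(fit$i0, 0, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  fit2 <- fit_current_time_relationship(I, 100 / (I - 1))
  expect_equal(fit2$k, 100, tolerance = 1e-4)
  expect_equal(fit2$i0, 1, tolerance = 1e-4)
  expect_equal(unname(predict(fit2, c(3, 7))), c(50, 100 / 6),
               tolerance = 1e-3)
})

test_that("input validation and trend diagnostics", {
  expect_error(fit_current_time_relationship(c(2, 5), c(60, 24)),
               "3 distinct currents")
  expect_error(fit_current_time_relationship(2:4, c(60, -1, 30)),
               "positive")
  expect_warning(fit_current_time_relationship(2:5, c(10, 20, 30, 40)),
                 "rank correlation")
})

test_that("cross-validation reports agreement between two fits", {
  I <- 2:15
  fa <- fit_current_time_relationship(I, 120 / I)
  same <- crossvalidate_relationship(fa, fa, I)
  expect_equal(same$max_abs_diff_s, 0)
  expect_equal(same$mean_abs_diff_s, 0)
  expect_equal(same$rel_k_diff, 0)

  fb <- fit_current_time_relationship(I, 240 / I)
  twice <- crossvalidate_relationship(fa, fb, I)
  expect_equal(twice$rel_k_diff, 1)
  expect_equal(twice$max_abs_diff_s, 60)      # at 2 mA: 120 vs 60 s

  fc <- fit_current_time_relationship(I, 100 / (I - 1))
  expect_error(crossvalidate_relationship(fa, fc, c(1, 5)),
               "exceed both fitted offsets")
})

test_that("train/test cohort fits agree on jittered synthetic t_max data", {
  set.seed(41)
  I <- 2:15
  mk_group <- function(n) {
    do.call(rbind, lapply(seq_len(n), function(s) {
      jit <- exp(rnorm(1, 0, 0.1))
      data.frame(I = I, t = 120 / I * jit * exp(rnorm(length(I), 0, 0.03)))
    }))
  }
  tra <- mk_group(5); tes <- mk_group(5)
  fa <- fit_current_time_relationship(tra$I, tra$t)
  fb <- fit_current_time_relationship(tes$I, tes$t)
  cmp <- crossvalidate_relationship(fa, fb, I)
  expect_lt(cmp$mean_abs_diff_s, 0.15 * mean(c(tra$t, tes$t)))
})

test_that("effect signs are recovered from planted parameter sweeps", {
  truth <- planted_truth()                 # current -, frequency -, pw +
  ref <- stim_protocol(12, 24, 200)
  mk <- function(cur, fr, pw)
    data.frame(current_mA = cur, frequency_Hz = fr, pulse_width_us = pw,
               t_max_s = planted_t_max(truth, stim_protocol(cur, fr, pw)))
  trials <- rbind(
    do.call(rbind, lapply(c(8, 10, 12, 14), function(i) mk(i, 24, 200))),
    do.call(rbind, lapply(c(16, 20, 28, 32), function(f) mk(12, f, 200))),
    do.call(rbind, lapply(c(100, 150, 250, 300), function(p) mk(12, 24, p))))
  eff <- parameter_effect_summary(trials, ref)
  expect_identical(eff$sign[eff$field == "current_mA"], "-")
  expect_identical(eff$sign[eff$field == "frequency_Hz"], "-")
  expect_identical(eff$sign[eff$field == "pulse_width_us"], "+")
})

test_that("degenerate and confounded effect designs are reported", {
  one <- data.frame(current_mA = 10, frequency_Hz = 24,
                    pulse_width_us = 200, t_max_s = 12)
  eff <- parameter_effect_summary(one)
  expect_true(all(eff$sign == "undefined"))

  conf <- data.frame(current_mA = c(12, 10), frequency_Hz = c(24, 30),
                     pulse_width_us = 200, t_max_s = c(10, 11))
  expect_error(parameter_effect_summary(conf), "confounded")
})
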