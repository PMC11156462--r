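test_that("generation is deterministic in the seed and leaves global RNG alone", {
  sp <- voluntary_trial_spec(seed = 99)
  a <- generate_voluntary_semg(sp)
  b <- generate_voluntary_semg(sp)
  expect_identical(a$samples, b$samples)

  fsp <- fes_trial_spec(seed = 99)
  fa <- generate_fes_mixed_signal(fsp)
  fb <- generate_fes_mixed_signal(fsp)
  expect_identical(fa$samples, fb$samples)

  set.seed(1); r1 <- runif(3)
  set.seed(1); invisible(generate_voluntary_semg(sp)); r2 <- runif(3)
  expect_identical(r1, r2)
})

test_that("a zero envelope yields an all-zero voluntary signal", {
  sp <- voluntary_trial_spec(envelope_scale = 0, noise_floor = 0, seed = 1)
  expect_identical(generate_voluntary_semg(sp)$samples, numeric(90000))
  expect_error(voluntary_trial_spec(duration = 30), "invalid spec")
  expect_error(voluntary_trial_spec(envelope_exponent = 0), "invalid spec")
})

test_that("voluntary windowed RMS tracks the planted power-law envelope", {
  sp <- voluntary_trial_spec(duration = 60, envelope_scale = 1,
                             envelope_exponent = 0.5, seed = 17)
  rec <- generate_voluntary_semg(sp)
  cv <- windowed_rms(rec, 1000)
  planted <- 1 * cv$times^0.5 + sp$noise_floor
  expect_gt(cor(cv$values, planted), 0.95)
  # spectral content essentially confined to the 20-450 Hz band
  in_band <- band_energy(rec$samples, rec$fs, 20, 450)
  total <- band_energy(rec$samples, rec$fs, 0, 500)
  expect_gt(in_band / total, 0.95)
})

test_that("FES pulse train matches the protocol pulse rate", {
  rec <- generate_fes_mixed_signal(fes_trial_spec(seed = 23))
  # artifact peaks dominate the mixed signal
  peaks <- which(rec$samples > 2)
  starts <- peaks[c(TRUE, diff(peaks) > 1)]
  expect_lt(abs(stats::median(diff(starts)) - 1000 / 24), 1)
})

test_that("planted evoked RMS peaks inside stage 3, at the requested time", {
  sp <- fes_trial_spec(seed = 29)
  rec <- generate_fes_mixed_signal(sp)
  pl <- attr(rec, "planted")
  # brute-force argmax of the planted envelope is the stage-3 knot
  tt <- seq(0, sp$duration, by = 1e-3)
  env <- fesfatigue:::.mwave_envelope(tt, pl$knot_times, pl$knot_values)
  expect_equal(tt[which.max(env)], planted_peak_time(sp), tolerance = 1e-3)
  # the ground-truth evoked component attains its windowed-RMS max there
  r <- windowed_rms(attr(rec, "evoked"))
  t_at_max <- r$times[which.max(r$values)]
  expect_gt(t_at_max, pl$knot_times[3])
  expect_lte(abs(t_at_max - planted_peak_time(sp)), 1)   # one RMS window
})

test_that("degenerate FES specs are rejected; silent spec gives noise only", {
  expect_error(fes_trial_spec(stage_durations = c(5, 7, 28)), "4 positive")
  expect_error(fes_trial_spec(stage_durations = c(5, 7, 28, 15),
                              duration = 40), "sum")
  expect_error(fes_trial_spec(stage_amplitudes = c(0.9, 0.3, 0.8, 0.4)),
               "global maximum")
  expect_error(generate_fes_mixed_signal(
    fes_trial_spec(protocol = stim_protocol(frequency_Hz = 0.05),
                   seed = 1)), "4 stimulation pulses")
  sp <- fes_trial_spec(stage_amplitudes = c(0, 0, 0, 0), base_level = 0,
                       artifact_amplitude = 0, seed = 3)
  rec <- generate_fes_mixed_signal(sp)
  expect_identical(attr(rec, "evoked")$samples, numeric(length(rec)))
  expect_gt(stats::sd(rec$samples), 0)      # background noise remains
})

test_that("cohort ground truth follows k/(I - i0) with per-subject jitter", {
  coh <- generate_cohort(3, currents = 10, seed = 5, jitter_sd = 0,
                         truth = planted_truth(k = 100, i0 = 0),
                         generate = FALSE)
  expect_equal(coh$truth$planted_t_max_s, rep(10, 3))

  coh2 <- generate_cohort(2, currents = 2:15, seed = 5, jitter_sd = 0,
                          generate = FALSE)
  for (s in unique(coh2$truth$subject)) {
    tp <- coh2$truth$planted_t_max_s[coh2$truth$subject == s]
    expect_true(all(diff(tp) < 0))
    expect_equal(tp, 120 / (2:15))
  }

  coh3 <- generate_cohort(4, currents = c(4, 8), seed = 9, jitter_sd = 0.2,
                          generate = FALSE)
  # one multiplicative factor per subject: within-subject ratio preserved
  rat <- with(coh3$truth, tapply(planted_t_max_s, subject,
                                 function(v) v[1] / v[2]))
  expect_equal(as.numeric(rat), rep(2, 4), tolerance = 1e-12)

  expect_error(generate_cohort(0, 2:15, generate = FALSE), "n_subjects")
  expect_error(generate_cohort(2, c(0, 5), truth = planted_truth(i0 = 1),
                               generate = FALSE), "exceed i0")
  same1 <- generate_cohort(2, c(5, 9), seed = 77, generate = FALSE)$truth
  same2 <- generate_cohort(2, c(5, 9), seed = 77, generate = FALSE)$truth
  expect_identical(same1, same2)
})

test_that("planted truth obeys the documented effect signs", {
  tr <- planted_truth()
  t_ref <- planted_t_max(tr, stim_protocol(12, 24, 200))
  expect_lt(planted_t_max(tr, stim_protocol(14, 24, 200)), t_ref)
  expect_lt(planted_t_max(tr, stim_protocol(12, 30, 200)), t_ref)
  expect_gt(planted_t_max(tr, stim_protocol(12, 24, 300)), t_ref)
  expect_error(planted_t_max(planted_truth(i0 = 3), stim_protocol(2)),
               "exceed i0")
  expect_error(planted_truth(freq_slope = 0.1), "freq_slope")
  expect_error(planted_truth(pw_slope = -1), "pw_slope")
})
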