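# every test that depends on the mother wavelet pins it explicitly
spec128 <- wavelet_spec(scale = 128, mother = "mexican_hat")

test_that("single-scale transform matches dense-grid integration", {
  set.seed(4)
  fs <- 1000
  x <- as.numeric(stats::filter(rnorm(2000), rep(1 / 3, 3), sides = 2))
  x[is.na(x)] <- 0
  x[c(300, 1100)] <- x[c(300, 1100)] + 5          # sharp transients too
  for (a in c(32, 128)) {
    sp <- wavelet_spec(scale = a, mother = "mexican_hat")
    got <- cwt_single_scale(semg_signal(x, fs), sp)$samples
    want <- oracle_cwt(x, a, fs)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-6)
  }
})

test_that("transform is linear and maps zero to zero", {
  fs <- 1000
  z <- cwt_single_scale(semg_signal(numeric(3000), fs), spec128)
  expect_equal(z$samples, numeric(3000))
  set.seed(5)
  f <- rnorm(3000); g <- rnorm(3000)
  wf <- cwt_single_scale(semg_signal(f, fs), spec128)$samples
  wg <- cwt_single_scale(semg_signal(g, fs), spec128)$samples
  wfg <- cwt_single_scale(semg_signal(2 * f + 3 * g, fs), spec128)$samples
  expect_lt(max(abs(wfg - (2 * wf + 3 * wg))) / max(abs(wfg)), 1e-9)
})

test_that("transform of the dilated wavelet peaks at its centre", {
  fs <- 1000; a <- 32; n <- 4000; tau0 <- 2000
  x <- mexican_hat(((0:(n - 1)) - tau0) / a) / sqrt(a)
  wt <- cwt_single_scale(semg_signal(x, fs),
                         wavelet_spec(scale = a, mother = "mexican_hat"))
  expect_lte(abs(which.max(abs(wt$samples)) - 1L - tau0), 1L)
})

test_that("transform commutes with time shifts away from boundaries", {
  set.seed(6)
  fs <- 1000; n <- 6000; s <- 500
  x <- rnorm(n)
  xs <- c(numeric(s), x)[1:n]                    # delay by s samples
  w1 <- cwt_single_scale(semg_signal(x, fs), spec128)$samples
  w2 <- cwt_single_scale(semg_signal(xs, fs), spec128)$samples
  L <- attr(cwt_single_scale(semg_signal(x, fs), spec128), "edge_samples")
  interior <- (L + s + 1):(n - L - s)
  expect_equal(w2[interior + s], w1[interior], tolerance = 1e-9)
})

test_that("over-dilated scales are rejected", {
  expect_error(cwt_single_scale(semg_signal(rnorm(100), 1000),
                                wavelet_spec(scale = 500)),
               "10x the record length")
})

test_that("separation recovers the evoked envelope from the mixed signal", {
  rec <- generate_fes_mixed_signal(fes_trial_spec(seed = 21))
  sep <- separate_evoked(rec, spec128)
  truth <- attr(rec, "evoked")
  r_sep <- windowed_rms(sep)$values
  r_tru <- windowed_rms(truth)$values
  expect_gt(cor(r_sep, r_tru), 0.8)
})

test_that("separation of a silent trial is silent", {
  sp <- fes_trial_spec(stage_amplitudes = c(0, 0, 0, 0), base_level = 0,
                       artifact_amplitude = 0, burst_noise_frac = 0,
                       noise_inband = 0, noise_broadband = 0, seed = 1)
  rec <- generate_fes_mixed_signal(sp)
  expect_equal(separate_evoked(rec, spec128)$samples,
               numeric(length(rec)))
})

test_that("separation suppresses the artifact's sharp transients", {
  rec <- generate_fes_mixed_signal(fes_trial_spec(seed = 22))
  sep <- separate_evoked(rec, spec128)
  hi_in <- band_energy(rec$samples, rec$fs, 100, 500) /
    band_energy(rec$samples, rec$fs, 0, 500)
  hi_out <- band_energy(sep$samples, rec$fs, 100, 500) /
    band_energy(sep$samples, rec$fs, 0, 500)
  expect_lt(hi_out, hi_in)
})
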