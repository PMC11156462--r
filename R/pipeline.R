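# High-level per-trial analyses and the file-based run drivers
# (simulate / analyze / report).

#' Analyse one FES trial end to end
#'
#' Chain: wavelet separation of the evoked sEMG (on the raw mixed
#' recording; the single-scale transform is itself the band-selective
#' step), windowed RMS, min-max normalisation, polynomial fit, M-wave
#' stage segmentation, maximum stimulation time.
#'
#' @param record A mixed-FES [semg_signal()].
#' @param wavelet A [wavelet_spec()].
#' @param window_samples RMS window length in samples.
#' @param degree Polynomial degree for the fatigue curve fit.
#' @return A list of class `fes_trial_analysis`: `rms`, `normalized`,
#'   `fit`, `segmentation`, `t_max`.
#' @export
analyze_fes_trial <- function(record, wavelet = wavelet_spec(),
                              window_samples = 1000, degree = 6) {
  sep <- separate_evoked(record, wavelet)
  rms <- windowed_rms(sep, window_samples)
  nrm <- minmax_normalize(rms)
  fit <- fit_polynomial_curve(nrm, degree)
  seg <- segment_mwave_stages(fit, nrm)
  structure(list(rms = rms, normalized = nrm, fit = fit, segmentation = seg,
                 t_max = max_stimulation_time(seg)),
            class = "fes_trial_analysis")
}

#' Analyse one voluntary trial end to end
#'
#' Chain: 20-450 Hz band-pass, terminal-segment extraction, windowed RMS,
#' power-function fit. The power law is fitted on the raw RMS curve (a
#' min-max normalised curve contains an exact zero, which the log-log
#' solver cannot represent); the normalised curve is returned alongside
#' for cross-subject overlays.
#'
#' @param record A voluntary [semg_signal()].
#' @param band Band-pass edges in hertz.
#' @param order Butterworth order.
#' @param terminal Terminal segment length in seconds.
#' @param window_samples RMS window length in samples.
#' @return A list of class `voluntary_trial_analysis`: `rms`, `normalized`,
#'   `fit`.
#' @export
analyze_voluntary_trial <- function(record, band = c(20, 450), order = 4,
                                    terminal = 60, window_samples = 1000) {
  seg <- extract_terminal_segment(bandpass_filter(record, band[1L], band[2L],
                                                  order), terminal)
  rms <- windowed_rms(seg, window_samples)
  nrm <- minmax_normalize(rms)
  fit <- fit_power_curve(rms)
  structure(list(rms = rms, normalized = nrm, fit = fit),
            class = "voluntary_trial_analysis")
}

#' @export
print.fes_trial_analysis <- function(x, ...) {
  cat("FES trial analysis\n")
  print(x$fit)
  cat(sprintf("maximum stimulation time: %.3f s\n", x$t_max))
  invisible(x)
}

#' @export
print.voluntary_trial_analysis <- function(x, ...) {
  cat("Voluntary trial analysis\n")
  print(x$fit)
  invisible(x)
}

.write_manifest <- function(path, params) {
  writeLines(sprintf("%s=%s", names(params),
                     vapply(params, function(v) paste(format(v),
                                                      collapse = ","), "")),
             path)
  invisible(path)
}

#' Simulate a cohort study to disk
#'
#' Writes voluntary and FES trial signals, the trial table, the
#' ground-truth table and a parameter manifest sufficient to reproduce the
#' run, then prints the seed used.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_subjects Subjects in the FES cohort.
#' @param currents FES currents in milliamperes.
#' @param truth A [planted_truth()].
#' @param seed Master seed.
#' @param jitter_sd Subject jitter (log scale).
#' @param n_voluntary Number of voluntary trials (default one per subject).
#' @param voluntary_duration Voluntary trial length in seconds.
#' @return Invisibly, a list with the trial-table and ground-truth paths.
#' @export
simulate_cohort <- function(out_dir, n_subjects = 10, currents = 2:15,
                            truth = planted_truth(), seed = 1,
                            jitter_sd = 0.05, n_voluntary = n_subjects,
                            voluntary_duration = 90) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  coh <- generate_cohort(n_subjects, currents, truth, seed = seed,
                         jitter_sd = jitter_sd)
  rows <- list()
  for (tr in coh$trials) {
    p <- tr$spec$protocol
    fn <- file.path(out_dir, sprintf("fes_%s_%05.1fmA.txt", tr$subject,
                                     p$current_mA))
    write_signal(tr$record, fn)
    rows[[length(rows) + 1L]] <-
      data.frame(subject_id = tr$subject, kind = "fes", path = fn,
                 current_mA = p$current_mA, frequency_Hz = p$frequency_Hz,
                 pulse_width_us = p$pulse_width_us)
  }
  vol_par <- .with_seed(seed + 1L,
                        data.frame(scale = exp(stats::rnorm(n_voluntary, 0, 0.3)),
                                   expo = stats::runif(n_voluntary, 0.4, 0.9)))
  for (s in seq_len(n_voluntary)) {
    vs <- voluntary_trial_spec(duration = voluntary_duration,
                               envelope_scale = vol_par$scale[s],
                               envelope_exponent = vol_par$expo[s],
                               seed = (seed + 7919L * s) %%
                                 .Machine$integer.max)
    rec <- generate_voluntary_semg(vs)
    rec$subject <- sprintf("S%02d", s)
    fn <- file.path(out_dir, sprintf("voluntary_S%02d.txt", s))
    write_signal(rec, fn)
    rows[[length(rows) + 1L]] <-
      data.frame(subject_id = rec$subject, kind = "voluntary", path = fn,
                 current_mA = NA_real_, frequency_Hz = NA_real_,
                 pulse_width_us = NA_real_)
  }
  tab_path <- file.path(out_dir, "trial_table.csv")
  write_trial_table(do.call(rbind, rows), tab_path)
  truth_path <- file.path(out_dir, "ground_truth.csv")
  utils::write.csv(coh$truth, truth_path, row.names = FALSE, quote = FALSE)
  .write_manifest(file.path(out_dir, "manifest.txt"),
                  list(seed = seed, n_subjects = n_subjects,
                       currents = currents, k = truth$k, i0 = truth$i0,
                       freq_slope = truth$freq_slope,
                       pw_slope = truth$pw_slope, jitter_sd = jitter_sd,
                       n_voluntary = n_voluntary,
                       voluntary_duration = voluntary_duration))
  message("simulated cohort with seed ", seed)
  invisible(list(trial_table = tab_path, ground_truth = truth_path))
}

.read_rms_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  tab <- utils::read.csv(path, comment.char = "#")
  rms_curve(tab$time_s, tab$rms,
            window_samples = as.integer(sub(".*window_samples=(\\d+).*",
                                            "\\1", hdr)),
            normalized = grepl("normalized=TRUE", hdr))
}

#' Analyse a simulated or recorded trial table
#'
#' Runs [analyze_voluntary_trial()] on every voluntary row and
#' [analyze_fes_trial()] on every FES row, writes per-trial normalised RMS
#' curves, a fit table, a segmentation table, the cohort-level
#' dose-duration fit (when at least three distinct currents are present)
#' and a run log recording every parameter. Unreadable or unanalysable
#' trials are skipped with a warning; the call fails only if every trial
#' fails.
#'
#' @param trial_table_path Path to a [read_trial_table()] CSV.
#' @param out_dir Output directory.
#' @param wavelet A [wavelet_spec()].
#' @param window_samples RMS window length in samples.
#' @param degree Polynomial degree for FES curve fits.
#' @param band,order Voluntary-branch band-pass settings.
#' @param terminal Voluntary terminal-segment length in seconds.
#' @return Invisibly, a list with the fit tables and (possibly `NULL`)
#'   dose-duration fit.
#' @export
analyze_trials <- function(trial_table_path, out_dir,
                           wavelet = wavelet_spec(), window_samples = 1000,
                           degree = 6, band = c(20, 450), order = 4,
                           terminal = 60) {
  tab <- read_trial_table(trial_table_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit_rows <- list(); seg_rows <- list(); n_fail <- 0L
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    res <- tryCatch({
      rec <- read_signal(row$path)
      if (row$kind == "voluntary") {
        an <- analyze_voluntary_trial(rec, band, order, terminal,
                                      window_samples)
        fit_rows[[length(fit_rows) + 1L]] <-
          data.frame(subject = row$subject_id, kind = "voluntary",
                     current_mA = NA_real_, a = coef(an$fit)[["a"]],
                     b = coef(an$fit)[["b"]], t_max_s = NA_real_,
                     r_squared = an$fit$r_squared,
                     p_value = an$fit$p_value)
      } else {
        an <- analyze_fes_trial(rec, wavelet, window_samples, degree)
        fit_rows[[length(fit_rows) + 1L]] <-
          data.frame(subject = row$subject_id, kind = "fes",
                     current_mA = row$current_mA, a = NA_real_,
                     b = NA_real_, t_max_s = an$t_max,
                     r_squared = an$fit$r_squared,
                     p_value = an$fit$p_value)
        b <- an$segmentation$boundaries
        seg_rows[[length(seg_rows) + 1L]] <-
          data.frame(subject = row$subject_id, current_mA = row$current_mA,
                     b1_s = b[1L], b2_s = b[2L], b3_s = b[3L],
                     peak_value = an$segmentation$peak_value)
      }
      write_rms_curve(an$normalized,
                      file.path(out_dir, sprintf("rms_%03d_%s.csv", i,
                                                 row$subject_id)))
      TRUE
    }, error = function(e) {
      warning("trial ", i, " (", row$path, ") skipped: ",
              conditionMessage(e), call. = FALSE)
      FALSE
    })
    if (!res) n_fail <- n_fail + 1L
  }
  if (n_fail == nrow(tab)) stop("all trials failed", call. = FALSE)
  fits <- do.call(rbind, fit_rows)
  utils::write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)
  if (length(seg_rows))
    utils::write.csv(do.call(rbind, seg_rows),
                     file.path(out_dir, "segmentations.csv"),
                     row.names = FALSE)
  rel <- NULL
  fes <- fits[fits$kind == "fes", ]
  if (nrow(fes) && length(unique(fes$current_mA)) >= 3L) {
    rel <- fit_current_time_relationship(fes$current_mA, fes$t_max_s)
    utils::write.csv(data.frame(k = rel$k, i0 = rel$i0,
                                r_squared = rel$r_squared,
                                p_value = rel$p_value),
                     file.path(out_dir, "relationship_fit.csv"),
                     row.names = FALSE)
  }
  .write_manifest(file.path(out_dir, "run_log.txt"),
                  list(trial_table = trial_table_path,
                       wavelet_scale = wavelet$scale,
                       wavelet_mother = wavelet$mother,
                       window_samples = window_samples, degree = degree,
                       band = band, filter_order = order,
                       terminal_s = terminal, n_trials = nrow(tab),
                       n_failed = n_fail))
  invisible(list(fits = fits, relationship = rel))
}

#' Render summary figures for an analysis directory
#'
#' Produces up to four PNG figures from the tables written by
#' [analyze_trials()]: the normalised voluntary fatigue-curve overlay with
#' power fits, the FES fatigue-curve overlay, one segmented M-wave
#' example, and the current vs maximum-stimulation-time scatter with the
#' fitted inverse-proportional curve. Missing inputs are listed and
#' skipped.
#'
#' @param analysis_dir Directory written by [analyze_trials()].
#' @param out_dir Figure directory (default: `analysis_dir`).
#' @return Invisibly, the paths of the figures rendered.
#' @export
render_report <- function(analysis_dir, out_dir = analysis_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  made <- character()
  fits_path <- file.path(analysis_dir, "fits.csv")
  if (!file.exists(fits_path)) {
    message("skipping report: missing ", fits_path)
    return(invisible(made))
  }
  fits <- utils::read.csv(fits_path)
  rms_files <- list.files(analysis_dir, "^rms_", full.names = TRUE)
  vol <- fits[fits$kind == "voluntary", ]
  if (nrow(vol)) {
    fp <- file.path(out_dir, "voluntary_fatigue_curves.png")
    grDevices::png(fp, 800, 600)
    graphics::plot(NA, xlim = c(0, 60), ylim = c(0, 1),
                   xlab = "time (s)", ylab = "normalized iRMS",
                   main = "Voluntary fatigue characteristic curves")
    tt <- seq(0.5, 60, by = 0.5)
    for (j in seq_len(nrow(vol)))
      graphics::lines(tt, pmin(1, pmax(0, vol$a[j] * tt^vol$b[j])),
                      col = j)
    grDevices::dev.off()
    made <- c(made, fp)
  }
  if (length(rms_files)) {
    fp <- file.path(out_dir, "fes_fatigue_curves.png")
    grDevices::png(fp, 800, 600)
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "relative time", ylab = "normalized RMS",
                   main = "FES fatigue characteristic curves")
    for (j in seq_along(rms_files)) {
      cv <- .read_rms_csv(rms_files[j])
      graphics::lines(cv$times / max(cv$times), cv$values,
                      col = grDevices::adjustcolor(j, 0.6))
    }
    grDevices::dev.off()
    made <- c(made, fp)
  }
  seg_path <- file.path(analysis_dir, "segmentations.csv")
  if (file.exists(seg_path) && length(rms_files)) {
    segs <- utils::read.csv(seg_path)
    fp <- file.path(out_dir, "mwave_stages.png")
    grDevices::png(fp, 800, 600)
    cv <- .read_rms_csv(rms_files[1L])
    graphics::plot(cv$times, cv$values, pch = 20, col = "grey40",
                   xlab = "time (s)", ylab = "normalized RMS",
                   main = "Four-stage M-wave decomposition")
    graphics::abline(v = unlist(segs[1L, c("b1_s", "b2_s", "b3_s")]),
                     lty = 2, col = "red")
    grDevices::dev.off()
    made <- c(made, fp)
  }
  fes <- fits[fits$kind == "fes", ]
  if (nrow(fes) >= 3L && length(unique(fes$current_mA)) >= 3L) {
    rel <- fit_current_time_relationship(fes$current_mA, fes$t_max_s)
    fp <- file.path(out_dir, "current_time_fit.png")
    grDevices::png(fp, 800, 600)
    graphics::plot(fes$current_mA, fes$t_max_s, xlab = "current (mA)",
                   ylab = "maximum stimulation time (s)",
                   main = sprintf("t(I) = %.1f / (I - %.2f)", rel$k,
                                  rel$i0))
    ii <- seq(min(fes$current_mA), max(fes$current_mA), length.out = 200)
    graphics::lines(ii, predict(rel, ii), col = "red", lwd = 2)
    grDevices::dev.off()
    made <- c(made, fp)
  }
  invisible(made)
}
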