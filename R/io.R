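# Native text dialect: UTF-8, "# key=value" header lines (fs mandatory),
# one sample per line.  Amplitudes are written with "%.17g" so that
# write -> read round-trips doubles bit-exactly.

#' Write an sEMG record to the native text format
#'
#' The format is self-describing plain text: `# key=value` header lines
#' (`fs` is mandatory; `channel`, `subject` and the protocol fields
#' `current_mA`, `frequency_Hz`, `pulse_width_us` are written when present)
#' followed by one sample per line at full double precision.
#'
#' @param record A [semg_signal()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @seealso [read_signal()]
#' @export
write_signal <- function(record, path) {
  if (!inherits(record, "semg_signal"))
    stop("'record' must be a semg_signal", call. = FALSE)
  if (length(record$samples) == 0L)
    stop("cannot write a record with no samples", call. = FALSE)
  hdr <- c(sprintf("# fs=%.17g", record$fs),
           sprintf("# channel=%s", record$channel))
  if (!is.null(record$subject))
    hdr <- c(hdr, sprintf("# subject=%s", record$subject))
  if (!is.null(record$protocol)) {
    p <- record$protocol
    hdr <- c(hdr,
             sprintf("# current_mA=%.17g", p$current_mA),
             sprintf("# frequency_Hz=%.17g", p$frequency_Hz),
             sprintf("# pulse_width_us=%.17g", p$pulse_width_us))
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(sprintf("%.17g", record$samples), con)
  invisible(path)
}

#' Read an sEMG record from the native text format
#'
#' @param path Path to a file written by [write_signal()] (or any file in the
#'   same dialect).
#' @return A [semg_signal()].
#' @export
read_signal <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  is_hdr <- startsWith(lines, "#")
  hdr <- sub("^#\\s*", "", lines[is_hdr])
  kv <- strsplit(hdr, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), "")
  get <- function(k) if (k %in% keys) vals[[match(k, keys)]] else NULL
  fs_txt <- get("fs")
  if (is.null(fs_txt))
    stop("format error: missing 'fs' header in ", path, call. = FALSE)
  fs <- suppressWarnings(as.numeric(fs_txt))
  if (is.na(fs) || fs <= 0)
    stop("format error: invalid sampling rate 'fs=", fs_txt, "'", call. = FALSE)
  data_lines <- which(!is_hdr & nzchar(trimws(lines)))
  if (length(data_lines) == 0L)
    stop("format error: no samples in ", path, call. = FALSE)
  x <- suppressWarnings(as.numeric(lines[data_lines]))
  if (anyNA(x)) {
    bad <- data_lines[which(is.na(x))[1L]]
    stop("format error: non-numeric sample at line ", bad, " of ", path,
         call. = FALSE)
  }
  proto <- NULL
  if (all(c("current_mA", "frequency_Hz", "pulse_width_us") %in% keys)) {
    proto <- stim_protocol(as.numeric(get("current_mA")),
                           as.numeric(get("frequency_Hz")),
                           as.numeric(get("pulse_width_us")))
  }
  semg_signal(x, fs = fs,
              channel = if (is.null(get("channel"))) "EMG1" else get("channel"),
              protocol = proto, subject = get("subject"))
}

#' Read a trial table
#'
#' Comma-separated table with header
#' `subject_id,kind,path,current_mA,frequency_Hz,pulse_width_us`. `kind` is
#' either `"voluntary"` or `"fes"`; `fes` rows must carry a complete
#' protocol, protocol fields on voluntary rows may be empty.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` with the columns above and class `trial_table`.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("format error: empty trial table", call. = FALSE)
  need <- c("subject_id", "kind", "path")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("format error: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(tab$kind), c("voluntary", "fes"))
  if (length(bad))
    stop("format error: unknown trial kind: ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (col in c("current_mA", "frequency_Hz", "pulse_width_us"))
    if (is.null(tab[[col]])) tab[[col]] <- NA_real_
  fes <- tab$kind == "fes"
  if (any(fes & (is.na(tab$current_mA) | is.na(tab$frequency_Hz) |
                 is.na(tab$pulse_width_us))))
    stop("format error: fes rows must carry a complete protocol",
         call. = FALSE)
  class(tab) <- c("trial_table", "data.frame")
  tab
}

#' Write a trial table
#'
#' @param table A data frame in the [read_trial_table()] layout.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_trial_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write an RMS curve as CSV
#'
#' Columns `time_s,rms`; a header comment line records the window length and
#' normalisation flag.
#'
#' @param curve An [rms_curve()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rms_curve <- function(curve, path) {
  stopifnot(inherits(curve, "rms_curve"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# window_samples=%d normalized=%s",
                     curve$window_samples, curve$normalized), con)
  writeLines("time_s,rms", con)
  writeLines(sprintf("%.17g,%.17g", curve$times, curve$values), con)
  invisible(path)
}
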