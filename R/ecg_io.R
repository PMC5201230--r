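# Reading and writing 12-lead ECG segments, annotations and results.
#
# Time convention used throughout the package: milliseconds from the start
# of the record (or beat), 0-based sample indexing, so sample i (1-based in
# R) sits at (i-1)/fs*1000 ms.  Windows are half-open [start, end).

REQUIRED_LEADS <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")

#' Construct an ECG record
#'
#' @param samples numeric matrix, one column per lead, amplitudes in
#'   microvolts.
#' @param fs sampling rate in Hz.
#' @param lead_names character vector of column labels; must contain at
#'   least the 8 independent leads I, II, V1-V6.
#' @return An object of class `ecg_record` with fields `samples`, `fs`,
#'   `lead_names` and `duration_s`.
#' @export
new_ecg_record <- function(samples, fs, lead_names = colnames(samples)) {
  samples <- as.matrix(samples)
  if (!is_finite_number(samples))
    jt_stop("jt_format_error", "ECG amplitudes must be finite numbers")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    jt_stop("jt_format_error", "fs must be a single positive number")
  if (is.null(lead_names) || length(lead_names) != ncol(samples))
    jt_stop("jt_format_error", "one lead name per column is required")
  missing <- setdiff(REQUIRED_LEADS, lead_names)
  if (length(missing))
    jt_stop("jt_format_error",
            sprintf("missing required lead(s): %s", paste(missing, collapse = ", ")))
  colnames(samples) <- lead_names
  structure(
    list(samples = samples, fs = fs, lead_names = lead_names,
         duration_s = nrow(samples) / fs),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d leads x %d samples @ %g Hz (%.2f s)\n",
              ncol(x$samples), nrow(x$samples), x$fs, x$duration_s))
  invisible(x)
}

#' Read a 12-lead ECG segment
#'
#' Reads either the package CSV dialect (a `# fs_hz=<fs> duration_s=<d>`
#' metadata line, a header row of lead names, one column per lead,
#' amplitudes in microvolts) or a WFDB record (`.hea` header plus
#' format-16 `.dat`, amplitudes rescaled to microvolts from the per-signal
#' gain).
#'
#' A declared duration that disagrees with `n_samples / fs` by more than
#' 0.1% is rejected as inconsistent.
#'
#' @param path file path (for WFDB, the `.hea` file or the record name).
#' @param format `"csv"` or `"wfdb"`.
#' @return An [new_ecg_record()] object.
#' @export
read_ecg <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "csv") read_ecg_csv(path) else read_ecg_wfdb(path)
}

read_ecg_csv <- function(path) {
  if (!file.exists(path)) jt_stop("jt_io_error", sprintf("file not found: %s", path))
  first <- readLines(path, n = 1)
  if (!grepl("^#", first))
    jt_stop("jt_format_error", "CSV ECG must start with a '# fs_hz=...' metadata line")
  meta <- parse_meta_line(first)
  if (is.null(meta$fs_hz))
    jt_stop("jt_format_error", "metadata line must declare fs_hz")
  dat <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  rec <- new_ecg_record(as.matrix(dat), fs = meta$fs_hz, lead_names = names(dat))
  if (!is.null(meta$duration_s)) check_duration(rec, meta$duration_s)
  rec
}

parse_meta_line <- function(line) {
  toks <- strsplit(sub("^#\\s*", "", line), "\\s+")[[1]]
  kv <- strsplit(toks, "=")
  out <- list()
  for (p in kv) if (length(p) == 2) out[[p[1]]] <- as.numeric(p[2])
  out
}

check_duration <- function(rec, declared_s) {
  actual <- nrow(rec$samples) / rec$fs
  if (abs(actual - declared_s) / declared_s > 0.001)
    jt_stop("jt_format_error",
            sprintf("declared duration %.3f s disagrees with %d samples at %g Hz (%.3f s) by >0.1%%",
                    declared_s, nrow(rec$samples), rec$fs, actual))
  invisible(rec)
}

#' Write an ECG record
#'
#' @param record an `ecg_record`.
#' @param path output path (CSV) or record base name (WFDB; writes
#'   `<path>.hea` and `<path>.dat`).
#' @param format `"csv"` or `"wfdb"`.
#' @param gain WFDB only: ADC units per millivolt (default 400, i.e. a
#'   2.5 uV amplitude resolution).  Amplitudes are rounded to this grid.
#' @return The path written, invisibly.
#' @export
write_ecg <- function(record, path, format = c("csv", "wfdb"), gain = 400) {
  format <- match.arg(format)
  stopifnot(inherits(record, "ecg_record"))
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# fs_hz=%g duration_s=%g", record$fs, record$duration_s), con)
    utils::write.csv(as.data.frame(record$samples), con, row.names = FALSE)
  } else {
    write_ecg_wfdb(record, path, gain)
  }
  invisible(path)
}

# --- minimal WFDB subset (header + format 16) ------------------------------
# No installed package reads WFDB in this language, so the subset the
# package emits (single .dat, format 16, gain(baseline)/uV syntax) is
# implemented directly.

write_ecg_wfdb <- function(record, path, gain = 400) {
  base <- sub("\\.hea$", "", path)
  recname <- basename(base)
  nsig <- ncol(record$samples)
  nsamp <- nrow(record$samples)
  adc <- round(record$samples * gain / 1000)  # uV -> ADU at gain ADU/mV
  if (any(abs(adc) > 32767))
    jt_stop("jt_format_error", "amplitude exceeds 16-bit WFDB range at this gain")
  hea <- c(
    sprintf("%s %d %g %d", recname, nsig, record$fs, nsamp),
    sprintf("%s.dat 16 %g(0)/uV 16 0 0 0 0 %s", recname, gain / 1000, record$lead_names)
  )
  writeLines(hea, paste0(base, ".hea"))
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(adc)), con, size = 2, endian = "little")
  invisible(base)
}

read_ecg_wfdb <- function(path) {
  base <- sub("\\.hea$", "", path)
  hea_path <- paste0(base, ".hea")
  if (!file.exists(hea_path)) jt_stop("jt_io_error", sprintf("file not found: %s", hea_path))
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  head_toks <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(head_toks[2])
  fs <- as.numeric(head_toks[3])
  nsamp <- as.integer(head_toks[4])
  if (length(lines) < 1 + nsig)
    jt_stop("jt_format_error", "WFDB header truncated")
  gains <- numeric(nsig); leads <- character(nsig); dats <- character(nsig)
  unit_scale <- numeric(nsig)   # multiply (ADU / gain) by this to get uV
  for (k in seq_len(nsig)) {
    toks <- strsplit(trimws(lines[1 + k]), "\\s+")[[1]]
    dats[k] <- toks[1]
    if (toks[2] != "16")
      jt_stop("jt_format_error", sprintf("unsupported WFDB signal format '%s' (only 16)", toks[2]))
    gspec <- toks[3]                                  # e.g. "0.4(0)/uV" or "200/mV"
    gains[k] <- as.numeric(sub("[(/].*$", "", gspec))
    unit <- if (grepl("/", gspec)) sub("^.*/", "", gspec) else "mV"
    unit_scale[k] <- switch(unit, uV = 1, mV = 1000,
                            jt_stop("jt_format_error",
                                    sprintf("unsupported WFDB unit '%s'", unit)))
    leads[k] <- toks[length(toks)]
  }
  if (length(unique(dats)) != 1)
    jt_stop("jt_format_error", "multi-file WFDB records are not supported")
  con <- file(file.path(dirname(hea_path), dats[1]), "rb")
  on.exit(close(con))
  raw <- readBin(con, "integer", n = nsig * nsamp, size = 2, endian = "little", signed = TRUE)
  adc <- matrix(raw, ncol = nsig, byrow = TRUE)
  uv <- sweep(adc, 2, unit_scale / gains, "*")  # ADU -> declared unit -> uV
  new_ecg_record(uv, fs = fs, lead_names = leads)
}

# --- annotations -----------------------------------------------------------

#' Read fiducial annotations
#'
#' CSV with columns `record_id`, `qrs_onset_ms`, `qrs_offset_ms` (and
#' optionally `t_peak_ms`, `t_end_ms`).  Times are relative to the QRS
#' trigger (R apex), so the QRS onset is typically negative and the
#' offset (J-point) positive.
#'
#' @param path CSV path.
#' @return data.frame of annotations with a `source` attribute of
#'   `"external"`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) jt_stop("jt_io_error", sprintf("file not found: %s", path))
  dat <- utils::read.csv(path)
  need <- c("record_id", "qrs_onset_ms", "qrs_offset_ms")
  missing <- setdiff(need, names(dat))
  if (length(missing))
    jt_stop("jt_format_error",
            sprintf("annotation file lacks column(s): %s", paste(missing, collapse = ", ")))
  bad <- dat$qrs_onset_ms >= dat$qrs_offset_ms
  if (any(bad))
    jt_stop("jt_format_error", "qrs_onset_ms must precede qrs_offset_ms in every row")
  attr(dat, "source") <- "external"
  dat
}

# --- results ---------------------------------------------------------------

#' Write delineation results
#'
#' One delimited-text row per beat.  All times are in milliseconds from the
#' start of the median beat, written in 3-decimal fixed format.
#' Unmeasurable beats get empty fiducial/interval fields and a reason code.
#' Output is deterministic: two writes of the same objects are
#' byte-identical.
#'
#' @param fiducials a `fiducial_set` or list of them (see
#'   [delineate_twave()]).
#' @param intervals matching `interval_set` or list of them; may be `NULL`
#'   for unmeasurable beats.
#' @param path output CSV path.
#' @param record_ids optional identifiers, recycled to the number of beats.
#' @return `path`, invisibly.
#' @export
write_results <- function(fiducials, intervals = NULL, path, record_ids = NULL) {
  if (inherits(fiducials, "fiducial_set")) fiducials <- list(fiducials)
  if (inherits(intervals, "interval_set")) intervals <- list(intervals)
  n <- length(fiducials)
  if (is.null(intervals)) intervals <- vector("list", n)
  if (length(intervals) != n)
    jt_stop("jt_input_error", "fiducials and intervals must have equal length")
  if (is.null(record_ids)) record_ids <- seq_len(n)
  record_ids <- rep_len(record_ids, n)

  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.3f", x))
  rows <- vapply(seq_len(n), function(i) {
    f <- fiducials[[i]]; iv <- intervals[[i]]
    if (!isTRUE(f$measurable)) {
      paste(record_ids[i], "", "", "", "", "", "", "", "", "", f$reason, sep = ",")
    } else {
      paste(record_ids[i],
            fmt(f$qrs_onset_ms), fmt(f$qrs_offset_ms), fmt(f$t_peak_ms),
            fmt(f$t_end_ms), as.integer(isTRUE(f$notched)),
            fmt(if (is.null(iv)) NA_real_ else iv$qt_ms),
            fmt(if (is.null(iv)) NA_real_ else iv$jtpeak_ms),
            fmt(if (is.null(iv)) NA_real_ else iv$tpeak_tend_ms),
            fmt(if (is.null(iv)) NA_real_ else iv$rr_ms),
            "", sep = ",")
    }
  }, character(1))

  header <- c(
    "# T-wave delineation results; times in ms from median-beat start, 0-based, 3-decimal fixed format",
    "# reason is empty for measurable beats, otherwise a machine-readable code",
    "record_id,qrs_onset_ms,qrs_offset_ms,t_peak_ms,t_end_ms,notched,qt_ms,jtpeak_ms,tpeak_tend_ms,rr_ms,reason"
  )
  con <- file(path, "wb")  # binary mode: fixed \n line endings for byte-identical reruns
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n")
  invisible(path)
}
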