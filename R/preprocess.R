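# Preprocessing: QRS triggers, baseline wander removal, median beats.

#' Detect QRS triggers
#'
#' Substitute energy-based QRS detector for records without external
#' annotations: zero-phase 5-25 Hz band-pass, squared derivative, adaptive
#' threshold at 30% of the running 2 s maximum, 200 ms refractory period.
#' Each detection is refined to the largest absolute band-passed deflection
#' (the R apex) within +/-40 ms.
#'
#' @param record an [new_ecg_record()] object, at least 3 s long.
#' @param config a [jt_config()]; see the `qrs` section.
#' @return Object of class `beat_triggers`: `trigger_samples` (1-based
#'   sample indices), `trigger_ms`, `rr_ms` (successive differences) and
#'   `median_rr_ms`.
#' @export
detect_qrs_triggers <- function(record, config = NULL) {
  stopifnot(inherits(record, "ecg_record"))
  config <- as_jt_config(config)
  cq <- config$qrs
  if (record$duration_s < 3)
    jt_stop("jt_input_error", "record must be at least 3 s long for QRS detection")
  lead <- if ("II" %in% record$lead_names) "II" else record$lead_names[1]
  x <- record$samples[, lead]
  fs <- record$fs
  if (max(x) - min(x) < 1e-6) jt_stop("jt_no_beats_error", "flat record: no QRS complexes found")
  bp <- bandpass_zerophase(x, cq$band_hz, fs)
  energy <- central_diff(bp, dt = 1000 / fs)^2
  win <- max(3L, as.integer(round(0.030 * fs)))      # 30 ms smoothing
  energy <- as.numeric(stats::filter(energy, rep(1 / win, win), sides = 2))
  energy[is.na(energy)] <- 0
  thr <- cq$threshold_frac * running_max(energy, as.integer(round(cq$running_max_ms / 1000 * fs / 2)))
  above <- energy > pmax(thr, 0.01 * max(energy))
  peaks <- local_maxima(energy)
  peaks <- peaks[above[peaks]]
  if (!length(peaks)) jt_stop("jt_no_beats_error", "no QRS complexes found")
  # refractory: greedy by amplitude
  refr <- cq$refractory_ms / 1000 * fs
  keep <- logical(length(peaks))
  for (i in order(energy[peaks], decreasing = TRUE)) {
    if (!any(keep & abs(peaks - peaks[i]) < refr)) keep[i] <- TRUE
  }
  peaks <- sort(peaks[keep])
  # refine to R apex on the band-passed signal
  halfw <- as.integer(round(0.040 * fs))
  trig <- vapply(peaks, function(p) {
    lo <- max(1L, p - halfw); hi <- min(length(bp), p + halfw)
    lo + which.max(abs(bp[lo:hi])) - 1L
  }, integer(1))
  trig <- sort(unique(trig))
  new_beat_triggers(trig, fs)
}

#' @rdname detect_qrs_triggers
#' @param trigger_samples strictly increasing 1-based sample indices.
#' @param fs sampling rate of the record the indices refer to.
#' @export
new_beat_triggers <- function(trigger_samples, fs) {
  trigger_samples <- as.integer(trigger_samples)
  if (is.unsorted(trigger_samples, strictly = TRUE))
    jt_stop("jt_input_error", "trigger samples must be strictly increasing")
  trigger_ms <- index_to_ms(trigger_samples, fs)
  rr_ms <- diff(trigger_ms)
  if (any(rr_ms <= 200))
    jt_stop("jt_input_error", "implausible RR interval <= 200 ms between triggers")
  structure(
    list(trigger_samples = trigger_samples, trigger_ms = trigger_ms,
         rr_ms = rr_ms, median_rr_ms = stats::median(rr_ms), fs = fs),
    class = "beat_triggers"
  )
}

#' @export
print.beat_triggers <- function(x, ...) {
  cat(sprintf("<beat_triggers> %d triggers, median RR %.0f ms\n",
              length(x$trigger_samples), x$median_rr_ms))
  invisible(x)
}

#' Remove baseline wander by cubic spline interpolation
#'
#' Places one isoelectric knot per beat at `trigger - knot_offset_ms`
#' (a PR-segment proxy), with the knot amplitude taken as the median over a
#' `knot_window_ms` window, fits an interpolating natural cubic spline
#' through the knots lead-wise, and subtracts it.  The residual at the knot
#' points is exactly zero by construction.
#'
#' @param record an `ecg_record`.
#' @param triggers a `beat_triggers` with at least 3 triggers.
#' @param config a [jt_config()].
#' @return A baseline-corrected `ecg_record`.
#' @export
remove_baseline <- function(record, triggers, config = NULL) {
  stopifnot(inherits(record, "ecg_record"), inherits(triggers, "beat_triggers"))
  config <- as_jt_config(config)
  cb <- config$baseline
  fs <- record$fs
  n <- nrow(record$samples)
  knot_idx <- triggers$trigger_samples - as.integer(round(cb$knot_offset_ms / 1000 * fs))
  halfw <- as.integer(round(cb$knot_window_ms / 2 / 1000 * fs))
  knot_idx <- knot_idx[knot_idx - halfw >= 1 & knot_idx + halfw <= n]
  if (length(knot_idx) < 3)
    jt_stop("jt_insufficient_beats_error",
            "need at least 3 in-bounds knots for baseline spline")
  corrected <- record$samples
  idx_all <- seq_len(n)
  for (lead in seq_len(ncol(corrected))) {
    y <- corrected[, lead]
    knots <- vapply(knot_idx, function(k) stats::median(y[(k - halfw):(k + halfw)]), numeric(1))
    sp <- stats::splinefun(knot_idx, knots, method = "fmm")
    corrected[, lead] <- y - sp(idx_all)
  }
  new_ecg_record(corrected, fs = fs, lead_names = record$lead_names)
}

#' Build the median beat
#'
#' Aligns beats on the QRS triggers using the window `[trigger - pre_ms,
#' trigger + min(post_max_ms, post_rr_frac * median RR))`, takes the
#' sample-wise median across aligned beats per lead (beats whose window
#' exceeds the record bounds are excluded), and upsamples the result to
#' 1 kHz by cubic spline interpolation so the returned beat has exactly
#' 1 ms resolution.
#'
#' @inheritParams remove_baseline
#' @return Object of class `median_beat`: `samples` (matrix at 1 kHz, uV),
#'   `lead_names`, `alignment_ms` (time of the QRS trigger within the
#'   beat), `median_rr_ms`, `n_beats_used`, `fs = 1000`.
#' @export
build_median_beat <- function(record, triggers, config = NULL) {
  stopifnot(inherits(record, "ecg_record"), inherits(triggers, "beat_triggers"))
  config <- as_jt_config(config)
  cm <- config$median
  fs <- record$fs
  n <- nrow(record$samples)
  pre <- as.integer(round(cm$pre_ms / 1000 * fs))
  post_ms <- min(cm$post_max_ms, cm$post_rr_frac * triggers$median_rr_ms)
  post <- as.integer(round(post_ms / 1000 * fs))
  usable <- triggers$trigger_samples[triggers$trigger_samples - pre >= 1 &
                                     triggers$trigger_samples + post <= n]
  if (length(usable) < cm$min_beats)
    jt_stop("jt_insufficient_beats_error",
            sprintf("only %d usable beat(s); need >= %d", length(usable), cm$min_beats))
  len <- pre + post + 1L
  med <- matrix(0, nrow = len, ncol = ncol(record$samples))
  for (lead in seq_len(ncol(record$samples))) {
    stack <- vapply(usable, function(tr) record$samples[(tr - pre):(tr + post), lead],
                    numeric(len))
    med[, lead] <- row_medians(stack)
  }
  # upsample to exactly 1 ms resolution
  t_orig <- index_to_ms(seq_len(len), fs)
  t_out <- seq(0, floor(t_orig[len]), by = 1)
  up <- matrix(0, nrow = length(t_out), ncol = ncol(med))
  for (lead in seq_len(ncol(med))) {
    up[, lead] <- stats::spline(t_orig, med[, lead], xout = t_out, method = "fmm")$y
  }
  colnames(up) <- record$lead_names
  new_median_beat(up, alignment_ms = cm$pre_ms,
                  median_rr_ms = triggers$median_rr_ms,
                  n_beats_used = length(usable))
}

#' @rdname build_median_beat
#' @param samples matrix of per-lead amplitudes (uV) at 1 kHz.
#' @param alignment_ms time of the QRS trigger within the beat (ms).
#' @param median_rr_ms median RR interval of the source record (ms).
#' @param n_beats_used number of beats entering the median.
#' @export
new_median_beat <- function(samples, alignment_ms, median_rr_ms, n_beats_used = NA_integer_) {
  samples <- as.matrix(samples)
  if (!is_finite_number(samples))
    jt_stop("jt_format_error", "median beat amplitudes must be finite")
  len_ms <- nrow(samples) - 1
  if (len_ms < alignment_ms + 0.6 * median_rr_ms)
    warning("median beat may be too short to contain the full T-wave search window")
  structure(
    list(samples = samples, lead_names = colnames(samples), fs = 1000,
         alignment_ms = alignment_ms, median_rr_ms = median_rr_ms,
         n_beats_used = n_beats_used),
    class = "median_beat"
  )
}

#' @export
print.median_beat <- function(x, ...) {
  cat(sprintf("<median_beat> %d leads x %d ms @ 1 kHz, alignment %g ms, median RR %.0f ms (%s beats)\n",
              ncol(x$samples), nrow(x$samples), x$alignment_ms, x$median_rr_ms,
              x$n_beats_used))
  invisible(x)
}
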