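# End-to-end convenience wrappers: record -> median beat -> vector
# magnitude -> fiducials -> intervals, and corpus-level delineation.

#' Process a 12-lead ECG record end to end
#'
#' Detects QRS triggers (unless supplied), removes baseline wander,
#' builds the 1 kHz median beat, derives the vector magnitude lead,
#' delineates the T-wave and measures intervals.  QRS onset/offset
#' annotations are trigger-relative (onset typically negative, offset
#' positive) and are mapped onto the median beat via its alignment point.
#'
#' @param record an `ecg_record`.
#' @param annotations list/row with `qrs_onset_ms`, `qrs_offset_ms`
#'   relative to the QRS trigger (required: the delineator needs the
#'   J-point).
#' @param config a [jt_config()].
#' @param tree a `relevance_tree` (default bundled).
#' @param triggers optional precomputed `beat_triggers` (skips the
#'   substitute detector).
#' @return List: `triggers`, `median_beat`, `vm`, `fiducials`,
#'   `intervals` (`NULL` when unmeasurable).
#' @export
process_record <- function(record, annotations, config = NULL, tree = NULL,
                           triggers = NULL) {
  config <- as_jt_config(config)
  if (is.null(triggers)) triggers <- detect_qrs_triggers(record, config)
  clean <- remove_baseline(record, triggers, config)
  beat <- build_median_beat(clean, triggers, config)
  vm <- vector_magnitude(transform_xyz(beat, config$vm$transform_matrix))
  ann <- as.list(annotations)
  beat_ann <- list(qrs_onset_ms = beat$alignment_ms + ann$qrs_onset_ms,
                   qrs_offset_ms = beat$alignment_ms + ann$qrs_offset_ms)
  fid <- delineate_twave(vm, beat_ann, config, tree)
  iv <- if (isTRUE(fid$measurable))
    measure_intervals(fid, triggers$median_rr_ms, config) else NULL
  list(triggers = triggers, median_beat = beat, vm = vm,
       fiducials = fid, intervals = iv)
}

#' Delineate every beat of a synthetic study
#'
#' Runs [delineate_twave()] on each corpus entry using the
#' generator-truth QRS annotations, and returns a long data.frame of
#' measured and true fiducials/intervals for evaluation.
#'
#' @param study a [generate_study()] result.
#' @param config a [jt_config()].
#' @param tree a `relevance_tree`.
#' @return data.frame: `subject`, `timepoint`, `replicate`, `measurable`,
#'   `t_peak_ms`, `t_end_ms`, `notched`, `jtpeak_ms`, `tpeak_tend_ms`,
#'   `qt_ms`, and the matching `*_true` columns.
#' @export
delineate_study <- function(study, config = NULL, tree = NULL) {
  stopifnot(inherits(study, "synthetic_study"))
  config <- as_jt_config(config)
  if (is.null(tree)) tree <- default_relevance_tree()
  rows <- lapply(study$entries, function(e) {
    tr <- e$truth
    fid <- delineate_twave(e$beat, list(qrs_onset_ms = tr$qrs_onset_ms,
                                        qrs_offset_ms = tr$qrs_offset_ms),
                           config, tree)
    meas <- isTRUE(fid$measurable)
    data.frame(
      subject = e$subject, timepoint = e$timepoint, replicate = e$replicate,
      measurable = meas,
      t_peak_ms = if (meas) fid$t_peak_ms else NA_real_,
      t_end_ms = if (meas) fid$t_end_ms else NA_real_,
      notched = isTRUE(fid$notched),
      jtpeak_ms = if (meas) fid$t_peak_ms - tr$qrs_offset_ms else NA_real_,
      tpeak_tend_ms = if (meas) fid$t_end_ms - fid$t_peak_ms else NA_real_,
      qt_ms = if (meas) fid$t_end_ms - tr$qrs_onset_ms else NA_real_,
      t_peak_true_ms = tr$t_peak_true_ms,
      t_end_true_ms = tr$t_end_true_ms,
      jtpeak_true_ms = tr$t_peak_true_ms - tr$qrs_offset_ms,
      tpeak_tend_true_ms = tr$t_end_true_ms - tr$t_peak_true_ms,
      notched_true = isTRUE(tr$notched),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
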