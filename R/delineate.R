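# Two-stage T-wave delineation on the vector magnitude lead.
#
# Stage 1 finds peak/slur candidates as pairs of local maximum-minimum in
# the first derivative of the low-pass filtered signal, classifies slurs
# for offset relevance with a decision tree, and applies cleanup rules;
# the T-peak is the highest surviving peak.  Stage 2 determines the T-wave
# offset by the tangent method and refines it over local minima of a
# cumulative energy signal with a distance/energy cost function.

#' Define the T-wave search window
#'
#' The window begins 25 ms after the J-point (QRS offset) and ends at 40%
#' of the preceding RR interval, measured from the QRS trigger (the only
#' rate-linked landmark in a median beat).  Half-open: `[start, end)`.
#'
#' @param j_point_ms QRS offset time within the beat (ms).
#' @param alignment_ms QRS trigger time within the beat (ms).
#' @param median_rr_ms preceding (median) RR interval (ms).
#' @param config a [jt_config()].
#' @return Object of class `search_window` with `start_ms`, `end_ms`.
#' @export
define_search_window <- function(j_point_ms, alignment_ms, median_rr_ms, config = NULL) {
  config <- as_jt_config(config)
  cd <- config$delineate
  if (median_rr_ms <= 0) jt_stop("jt_input_error", "median RR must be positive")
  start_ms <- j_point_ms + cd$window_start_offset_ms
  end_ms <- alignment_ms + cd$window_rr_frac * median_rr_ms
  if (end_ms <= start_ms)
    jt_stop("jt_degenerate_window",
            sprintf("degenerate search window [%g, %g): beat unmeasurable", start_ms, end_ms))
  structure(list(start_ms = start_ms, end_ms = end_ms), class = "search_window")
}

#' Smoothed first derivative of the vector magnitude lead
#'
#' Zero-phase 4th-order Butterworth low-pass (default 25 Hz cutoff)
#' followed by central differences.  Zero phase preserves fiducial timing.
#'
#' @param vm a `vm_beat` at 1 kHz.
#' @param config a [jt_config()].
#' @return Object of class `vm_derivative`: `smoothed` (filtered vm, uV),
#'   `deriv` (uV/ms), both the same length as the input.
#' @export
smooth_derivative <- function(vm, config = NULL) {
  stopifnot(inherits(vm, "vm_beat"))
  config <- as_jt_config(config)
  sm <- lowpass_zerophase(vm$vm, config$delineate$lowpass_hz, vm$fs)
  structure(list(smoothed = sm, deriv = central_diff(sm, dt = 1), fs = vm$fs),
            class = "vm_derivative")
}

as_vm_derivative <- function(vm, deriv, config) {
  if (is.null(deriv)) smooth_derivative(vm, config) else deriv
}

#' Find T-wave peak/slur candidates
#'
#' All pairs of (local maximum, following local minimum) of the smoothed
#' first derivative inside the search window are candidates.  A candidate
#' is retained if it is at least 10 ms wide (narrower pairs are noise),
#' its apex (highest amplitude between the two derivative extrema) reaches
#' the 100 uV minimum detection voltage, and it lies inside the window
#' (rise and apex inside `[start, end)`; the falling derivative extremum
#' may extend up to 150 ms past the window end).  Each retained candidate
#' is labelled `peak` or `slur` by [classify_candidate()].
#'
#' @param vm a `vm_beat`.
#' @param window a [define_search_window()] result.
#' @param deriv optional precomputed [smooth_derivative()] result.
#' @param config a [jt_config()].
#' @return A data.frame of class `jt_candidates` with columns `rise_ms`,
#'   `fall_ms`, `apex_ms`, `apex_uv`, `width_ms`, `label`, ordered by
#'   `rise_ms`.  Zero rows if nothing qualifies.
#' @export
find_candidates <- function(vm, window, deriv = NULL, config = NULL) {
  stopifnot(inherits(vm, "vm_beat"), inherits(window, "search_window"))
  config <- as_jt_config(config)
  cd <- config$delineate
  deriv <- as_vm_derivative(vm, deriv, config)
  d <- deriv$deriv; sm <- deriv$smoothed
  n <- length(d)
  lo <- max(2L, ms_to_index(window$start_ms, vm$fs))
  hi <- min(n - 1L, ms_to_index(window$end_ms, vm$fs) + 150L)
  if (hi <= lo) return(empty_candidates())
  seg <- lo:hi
  maxima <- seg[1] - 1L + local_maxima(d[seg])
  minima <- seg[1] - 1L + local_minima(d[seg])
  rows <- list()
  for (m in maxima) {
    fol <- minima[minima > m]
    if (!length(fol)) next
    f <- fol[1]
    apex_idx <- m - 1L + which.max(sm[m:f])
    cand <- data.frame(
      rise_ms = index_to_ms(m, vm$fs), fall_ms = index_to_ms(f, vm$fs),
      apex_ms = index_to_ms(apex_idx, vm$fs), apex_uv = sm[apex_idx],
      width_ms = index_to_ms(f, vm$fs) - index_to_ms(m, vm$fs),
      stringsAsFactors = FALSE
    )
    if (cand$width_ms < cd$min_width_ms) next
    if (cand$apex_uv < cd$min_voltage_uv) next
    if (cand$rise_ms < window$start_ms || cand$rise_ms >= window$end_ms) next
    if (cand$apex_ms >= window$end_ms) next
    rows[[length(rows) + 1L]] <- cand
  }
  if (!length(rows)) return(empty_candidates())
  out <- do.call(rbind, rows)
  out <- out[order(out$rise_ms), , drop = FALSE]
  out$label <- vapply(seq_len(nrow(out)), function(i)
    classify_candidate(out[i, ], deriv), character(1))
  rownames(out) <- NULL
  class(out) <- c("jt_candidates", "data.frame")
  out
}

empty_candidates <- function() {
  out <- data.frame(rise_ms = numeric(0), fall_ms = numeric(0),
                    apex_ms = numeric(0), apex_uv = numeric(0),
                    width_ms = numeric(0), label = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("jt_candidates", "data.frame")
  out
}

#' Label a candidate as peak or slur
#'
#' A candidate is a `peak` if the first derivative crosses the zero line
#' between its bounding derivative extrema (the signal has a true local
#' maximum there), otherwise a `slur` (the derivative dips but keeps its
#' sign: a shoulder on a limb).
#'
#' @param candidate one row of a [find_candidates()] data.frame (or any
#'   list with `rise_ms`, `fall_ms`).
#' @param deriv a [smooth_derivative()] result.
#' @return `"peak"` or `"slur"`.
#' @export
classify_candidate <- function(candidate, deriv) {
  fs <- deriv$fs
  d <- deriv$deriv[ms_to_index(candidate$rise_ms, fs):ms_to_index(candidate$fall_ms, fs)]
  if (max(d) > 0 && min(d) < 0) "peak" else "slur"
}

# Limb slope of a candidate: least-squares fit of the smoothed signal
# between the derivative extremum and the apex; where that segment is
# degenerate (< 3 samples, e.g. the rising limb of a descending-limb slur
# whose apex coincides with its rise point) the instantaneous derivative
# at the extremum is used.  Returns slope (uV/ms) and the line
# c(intercept, slope) in beat-ms coordinates.
limb_line <- function(from_ms, to_ms, at_ms, deriv) {
  fs <- deriv$fs
  i0 <- ms_to_index(from_ms, fs); i1 <- ms_to_index(to_ms, fs)
  if (i1 - i0 >= 2) {
    t <- index_to_ms(i0:i1, fs)
    fit_line(t, deriv$smoothed[i0:i1])
  } else {
    ia <- ms_to_index(at_ms, fs)
    sl <- deriv$deriv[ia]
    c(deriv$smoothed[ia] - sl * index_to_ms(ia, fs), sl)
  }
}

candidate_limbs <- function(candidate, deriv) {
  rising <- limb_line(candidate$rise_ms, candidate$apex_ms, candidate$rise_ms, deriv)
  falling <- limb_line(candidate$apex_ms, candidate$fall_ms, candidate$fall_ms, deriv)
  if (any(!is.finite(c(rising, falling))))
    jt_stop("jt_feature_error", "degenerate candidate limb")
  list(rising = rising, falling = falling)
}

#' Apply candidate cleanup rules
#'
#' Three rules, in order, each with a configurable threshold:
#' \enumerate{
#'   \item \emph{merge}: two adjacent candidates are merged when the
#'     lowest amplitude between their apexes is at least
#'     `merge_valley_frac` (default 0.90) of the lower apex -- the
#'     "valley" is then close to the peaks and the pair is one deflection;
#'   \item \emph{remove}: a peak is removed when its apex falls short of
#'     the highest peak by more than `remove_diff_frac` (default 0.50) of
#'     the highest apex;
#'   \item \emph{convert}: a peak is relabelled slur when either limb is
#'     almost horizontal (absolute limb angle below
#'     `horizontal_angle_deg`, default 5 degrees, with time in ms and
#'     amplitude in uV).
#' }
#'
#' @param candidates a `jt_candidates` data.frame.
#' @param deriv the matching [smooth_derivative()] result.
#' @param config a [jt_config()].
#' @return The cleaned `jt_candidates`, still ordered by time.
#' @export
apply_cleanup_rules <- function(candidates, deriv, config = NULL) {
  config <- as_jt_config(config)
  cd <- config$delineate
  sm <- deriv$smoothed; fs <- deriv$fs
  # -- merge ----------------------------------------------------------------
  repeat {
    if (nrow(candidates) < 2) break
    merged <- FALSE
    for (i in seq_len(nrow(candidates) - 1L)) {
      a <- candidates[i, ]; b <- candidates[i + 1L, ]
      ia <- ms_to_index(a$apex_ms, fs); ib <- ms_to_index(b$apex_ms, fs)
      if (ib - ia < 2L) next
      between <- sm[ia:ib]
      vi <- which.min(between)
      # a true valley is interior; the monotone descent onto a trailing
      # slur attains its minimum at the slur apex and must not merge
      if (vi == 1L || vi == length(between)) next
      valley <- between[vi]
      if (valley >= cd$merge_valley_frac * min(a$apex_uv, b$apex_uv)) {
        i0 <- ms_to_index(a$rise_ms, fs); i1 <- ms_to_index(b$fall_ms, fs)
        apex_idx <- i0 - 1L + which.max(sm[i0:i1])
        nc <- data.frame(rise_ms = a$rise_ms, fall_ms = b$fall_ms,
                         apex_ms = index_to_ms(apex_idx, fs),
                         apex_uv = sm[apex_idx],
                         width_ms = b$fall_ms - a$rise_ms,
                         label = NA_character_, stringsAsFactors = FALSE)
        nc$label <- classify_candidate(nc, deriv)
        candidates <- rbind(
          if (i > 1) candidates[seq_len(i - 1L), ],
          nc,
          if (i + 1L < nrow(candidates)) candidates[(i + 2L):nrow(candidates), ]
        )
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  # -- remove ---------------------------------------------------------------
  is_peak <- candidates$label == "peak"
  if (any(is_peak)) {
    amax <- max(candidates$apex_uv[is_peak])
    drop <- is_peak & (amax - candidates$apex_uv) > cd$remove_diff_frac * amax
    candidates <- candidates[!drop, , drop = FALSE]
  }
  # -- convert --------------------------------------------------------------
  for (i in seq_len(nrow(candidates))) {
    if (candidates$label[i] != "peak") next
    limbs <- tryCatch(candidate_limbs(candidates[i, ], deriv),
                      jt_feature_error = function(e) NULL)
    if (is.null(limbs)) next
    if (abs(atand(limbs$rising[2])) < cd$horizontal_angle_deg ||
        abs(atand(limbs$falling[2])) < cd$horizontal_angle_deg)
      candidates$label[i] <- "slur"
  }
  rownames(candidates) <- NULL
  class(candidates) <- c("jt_candidates", "data.frame")
  candidates
}

#' Select the T-wave peak
#'
#' The T-peak is the apex of the highest-amplitude surviving peak after
#' cleanup (ties break to the earliest).  If more than one peak survives,
#' the beat is flagged notched and the highest non-selected peak is
#' reported as the secondary peak.
#'
#' @param candidates cleaned `jt_candidates`.
#' @return List with `t_peak_ms`, `secondary_peak_ms` (`NA` if none),
#'   `notched`, `n_peaks`.
#' @export
select_tpeak <- function(candidates) {
  peaks <- candidates[candidates$label == "peak", , drop = FALSE]
  if (!nrow(peaks))
    jt_stop("jt_unmeasurable", "no surviving peak", reason = "no_surviving_peak")
  best <- which(peaks$apex_uv == max(peaks$apex_uv))[1]
  secondary <- NA_real_
  if (nrow(peaks) > 1) {
    rest <- peaks[-best, , drop = FALSE]
    secondary <- rest$apex_ms[which.max(rest$apex_uv)]
  }
  list(t_peak_ms = peaks$apex_ms[best], secondary_peak_ms = secondary,
       notched = nrow(peaks) > 1, n_peaks = nrow(peaks))
}

#' Initial T-wave offset by the tangent method
#'
#' Finds the steepest descending slope of the (smoothed) vector magnitude
#' after the last candidate's apex and intersects the tangent line at that
#' point with the isoelectric level (0 uV after baseline removal;
#' configurable).
#'
#' @param vm a `vm_beat`.
#' @param last_candidate the last relevant candidate (row of
#'   `jt_candidates`).
#' @param deriv optional precomputed [smooth_derivative()].
#' @param config a [jt_config()].
#' @return `t_end_initial_ms` (numeric scalar, ms; may be fractional).
#' @export
tangent_offset <- function(vm, last_candidate, deriv = NULL, config = NULL) {
  stopifnot(inherits(vm, "vm_beat"))
  config <- as_jt_config(config)
  cd <- config$delineate
  deriv <- as_vm_derivative(vm, deriv, config)
  n <- length(deriv$deriv)
  beat_end_ms <- index_to_ms(n, vm$fs)
  apex_idx <- ms_to_index(last_candidate$apex_ms, vm$fs)
  if (beat_end_ms - last_candidate$apex_ms < cd$min_tail_ms)
    jt_stop("jt_unmeasurable", "apex too close to beat end for offset determination",
            reason = "tail_too_short")
  hi <- min(n, apex_idx + as.integer(cd$tangent_search_ms))
  rng <- (apex_idx + 1L):hi
  steep <- rng[which.min(deriv$deriv[rng])]
  slope <- deriv$deriv[steep]
  if (slope >= 0)
    jt_stop("jt_unmeasurable", "no descending limb after the last candidate",
            reason = "no_descending_limb")
  t_s <- index_to_ms(steep, vm$fs)
  t_end <- t_s - (deriv$smoothed[steep] - cd$baseline_level_uv) / slope
  min(t_end, beat_end_ms)
}

#' Cumulative energy signal over the offset-search interval
#'
#' A cumulative amplitude signal built from the smoothed first derivative
#' over `[interval[1], interval[2]]`: the signal decrements by the
#' derivative magnitude where the derivative increases sample-to-sample
#' and increments by it otherwise, then is min-max normalized to `[0, 1]`.
#' Along a convex decaying T-wave tail the result decreases monotonically
#' from 1 at the window start to 0 at the end; a flat shelf followed by a
#' drop produces an interior local minimum at the shelf end -- these
#' minima are the alternative offset candidates.
#'
#' @param vm a `vm_beat`.
#' @param interval numeric length-2, `(start_ms, end_ms)` -- normally the
#'   last candidate's falling derivative extremum and the tangent offset.
#' @param deriv optional precomputed [smooth_derivative()].
#' @param config a [jt_config()].
#' @return An `energy_signal` object (`times_ms`, `values`,
#'   `candidate_minima_ms`), or `NULL` when the interval is shorter than
#'   `min_energy_interval_ms` or the raw energy is degenerate (constant) --
#'   the caller then keeps the tangent offset.
#' @export
energy_signal <- function(vm, interval, deriv = NULL, config = NULL) {
  stopifnot(inherits(vm, "vm_beat"))
  config <- as_jt_config(config)
  cd <- config$delineate
  deriv <- as_vm_derivative(vm, deriv, config)
  n <- length(deriv$deriv)
  a <- max(1L, ms_to_index(interval[1], vm$fs))
  b <- min(n, ms_to_index(interval[2], vm$fs))
  if (index_to_ms(b, vm$fs) - index_to_ms(a, vm$fs) < cd$min_energy_interval_ms)
    return(NULL)
  d <- deriv$deriv[a:b]
  step <- ifelse(diff(d) > 0, -abs(d[-1]), abs(d[-1]))
  e <- c(0, cumsum(step))
  rng <- max(e) - min(e)
  if (rng < 1e-9) return(NULL)
  values <- (e - min(e)) / rng
  times <- index_to_ms(a:b, vm$fs)
  minima <- local_minima(values)
  structure(
    list(times_ms = times, values = values,
         candidate_minima_ms = times[minima]),
    class = "energy_signal"
  )
}

#' Refine the T-wave offset with the distance/energy cost function
#'
#' Offset candidates are the interior local minima of the energy signal
#' plus the tangent offset itself.  The chosen offset minimizes
#' `w1 * (c - t_peak) / (next_qrs - t_peak) + w2 * E(c)`; ties break to
#' the earliest candidate.  The result never precedes the T-peak.
#'
#' @param energy an [energy_signal()] result (or `NULL` to keep the
#'   tangent offset).
#' @param t_peak_ms T-peak time (ms).
#' @param next_qrs_ms projected time of the next QRS complex (for a median
#'   beat: `alignment_ms + median_rr_ms`).
#' @param t_end_initial_ms the tangent offset.
#' @param config a [jt_config()]; weights `w1`, `w2`.
#' @return `t_end_ms`.
#' @export
refine_offset <- function(energy, t_peak_ms, next_qrs_ms, t_end_initial_ms,
                          config = NULL) {
  config <- as_jt_config(config)
  cd <- config$delineate
  if (is.null(energy)) return(t_end_initial_ms)
  cands <- sort(unique(c(energy$candidate_minima_ms, t_end_initial_ms)))
  cands <- cands[cands > t_peak_ms]
  if (!length(cands)) return(t_end_initial_ms)
  e_at <- function(t) {
    t0 <- pmin(pmax(t, energy$times_ms[1]), energy$times_ms[length(energy$times_ms)])
    stats::approx(energy$times_ms, energy$values, xout = t0, rule = 2)$y
  }
  cost <- cd$w1 * (cands - t_peak_ms) / (next_qrs_ms - t_peak_ms) + cd$w2 * e_at(cands)
  best <- which(cost <= min(cost) + 1e-12)[1]  # earliest among ties
  cands[best]
}

#' Delineate the T-wave on a vector magnitude beat
#'
#' Full pipeline: search window, candidate detection, peak/slur labelling,
#' cleanup rules (merge, remove, convert), slur-relevance classification
#' for slurs trailing the last peak, T-peak selection, tangent offset and
#' energy-cost refinement.  Deterministic for fixed input, config and
#' tree.  Degenerate inputs never raise: the returned fiducial set carries
#' `measurable = FALSE` plus a machine-readable reason code
#' (`degenerate_window`, `no_candidates`, `no_surviving_peak`,
#' `tail_too_short`, `no_descending_limb`, `offset_before_peak`).
#'
#' @param vm a `vm_beat`.
#' @param annotations list (or one-row data.frame) with `qrs_onset_ms` and
#'   `qrs_offset_ms` in beat coordinates (ms from beat start).  The QRS
#'   offset (J-point) is required; the onset is only carried through for
#'   interval computation.
#' @param config a [jt_config()].
#' @param tree a `relevance_tree` (default: the bundled tree).
#' @return Object of class `fiducial_set`: `qrs_onset_ms`,
#'   `qrs_offset_ms`, `t_peak_ms`, `secondary_peak_ms`, `notched`,
#'   `t_end_ms`, `t_end_tangent_ms`, `measurable`, `reason` and a
#'   `diagnostics` list (`n_candidates`, `n_peaks`, `n_relevant_slurs`,
#'   `apex_uv`).
#' @export
delineate_twave <- function(vm, annotations, config = NULL, tree = NULL) {
  stopifnot(inherits(vm, "vm_beat"))
  config <- as_jt_config(config)
  if (is.null(tree)) tree <- default_relevance_tree()
  ann <- as.list(annotations)
  if (is.null(ann$qrs_offset_ms) || is.na(ann$qrs_offset_ms))
    jt_stop("jt_input_error", "QRS offset (J-point) annotation is required")
  onset <- if (is.null(ann$qrs_onset_ms)) NA_real_ else ann$qrs_onset_ms
  if (!is.na(onset) && onset >= ann$qrs_offset_ms)
    jt_stop("jt_input_error", "QRS onset must precede QRS offset")

  unmeasurable <- function(reason, diagnostics = list()) {
    structure(
      list(qrs_onset_ms = onset, qrs_offset_ms = ann$qrs_offset_ms,
           t_peak_ms = NA_real_, secondary_peak_ms = NA_real_, notched = FALSE,
           t_end_ms = NA_real_, t_end_tangent_ms = NA_real_,
           measurable = FALSE, reason = reason, diagnostics = diagnostics),
      class = "fiducial_set"
    )
  }
  cond_reason <- function(e) if (!is.null(e$reason)) e$reason else conditionMessage(e)

  window <- tryCatch(
    define_search_window(ann$qrs_offset_ms, vm$alignment_ms, vm$median_rr_ms, config),
    jt_degenerate_window = function(e) NULL
  )
  if (is.null(window)) return(unmeasurable("degenerate_window"))

  deriv <- smooth_derivative(vm, config)
  cands <- find_candidates(vm, window, deriv, config)
  if (!nrow(cands)) return(unmeasurable("no_candidates"))
  cands <- apply_cleanup_rules(cands, deriv, config)

  diagnostics <- list(n_candidates = nrow(cands),
                      n_peaks = sum(cands$label == "peak"),
                      n_relevant_slurs = 0L,
                      apex_uv = cands$apex_uv)

  sel <- tryCatch(select_tpeak(cands), jt_unmeasurable = function(e) e)
  if (inherits(sel, "condition")) return(unmeasurable(cond_reason(sel), diagnostics))

  # slurs are only useful for the offset when they trail the last peak
  peak_rows <- which(cands$label == "peak")
  last_peak_row <- peak_rows[length(peak_rows)]
  trailing <- which(cands$label == "slur" & seq_len(nrow(cands)) > last_peak_row)
  relevant_rows <- integer(0)
  for (i in trailing) {
    verdict <- tryCatch({
      feats <- compute_slur_features(cands[last_peak_row, ], cands[i, ], vm, deriv, config)
      classify_slur_relevance(feats, tree)
    }, jt_feature_error = function(e) "irrelevant",
       jt_classification_error = function(e) "irrelevant")
    if (identical(verdict, "relevant")) relevant_rows <- c(relevant_rows, i)
  }
  diagnostics$n_relevant_slurs <- length(relevant_rows)
  last_row <- if (length(relevant_rows)) max(relevant_rows) else last_peak_row

  t_end_tangent <- tryCatch(
    tangent_offset(vm, cands[last_row, ], deriv, config),
    jt_unmeasurable = function(e) e
  )
  if (inherits(t_end_tangent, "condition"))
    return(unmeasurable(cond_reason(t_end_tangent), diagnostics))

  next_qrs_ms <- vm$alignment_ms + vm$median_rr_ms
  energy <- energy_signal(vm, c(cands$fall_ms[last_row], t_end_tangent), deriv, config)
  t_end <- refine_offset(energy, sel$t_peak_ms, next_qrs_ms, t_end_tangent, config)
  if (t_end <= sel$t_peak_ms) t_end <- t_end_tangent
  if (t_end <= sel$t_peak_ms) return(unmeasurable("offset_before_peak", diagnostics))

  structure(
    list(qrs_onset_ms = onset, qrs_offset_ms = ann$qrs_offset_ms,
         t_peak_ms = sel$t_peak_ms, secondary_peak_ms = sel$secondary_peak_ms,
         notched = sel$notched, t_end_ms = t_end,
         t_end_tangent_ms = t_end_tangent,
         measurable = TRUE, reason = "", diagnostics = diagnostics),
    class = "fiducial_set"
  )
}

#' @export
print.fiducial_set <- function(x, ...) {
  if (!isTRUE(x$measurable)) {
    cat(sprintf("<fiducial_set> unmeasurable (%s)\n", x$reason))
  } else {
    cat(sprintf("<fiducial_set> Tpeak %.1f ms, Tend %.1f ms%s (J %.1f ms)\n",
                x$t_peak_ms, x$t_end_ms,
                if (isTRUE(x$notched)) sprintf(", notched (secondary %.1f ms)", x$secondary_peak_ms) else "",
                x$qrs_offset_ms))
  }
  invisible(x)
}
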