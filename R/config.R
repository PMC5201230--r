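#' Configuration for the measurement pipeline
#'
#' Builds the nested list of tunable parameters used throughout the
#' preprocessing, vector-magnitude and delineation chain.  Every value has a
#' default; supply named sublists to override individual entries, e.g.
#' `jt_config(delineate = list(merge_valley_frac = 0.85))`.
#'
#' @param baseline baseline-removal settings: `knot_offset_ms` (knot placed
#'   this far before each QRS trigger, PR-segment proxy; default 80),
#'   `knot_window_ms` (width of the median window defining each knot
#'   amplitude; default 20).
#' @param qrs substitute QRS detector settings: `band_hz` (pass band of the
#'   zero-phase pre-filter, default 5-25 Hz), `refractory_ms` (minimum
#'   trigger spacing, default 200), `threshold_frac` (detection threshold as
#'   a fraction of the running 2 s energy maximum, default 0.3).
#' @param median median-beat settings: window `[trigger - pre_ms,
#'   trigger + min(post_max_ms, post_rr_frac * median RR)]`, minimum usable
#'   beats `min_beats`.
#' @param vm `transform_matrix`: a 3x8 matrix (rows X, Y, Z; columns I, II,
#'   V1-V6) or `NULL` for the bundled default (see [default_xyz_matrix()]).
#' @param delineate T-wave delineation settings; the load-bearing ones are
#'   `window_start_offset_ms` (25 ms after the J-point),
#'   `window_rr_frac` (window ends at this fraction of the preceding RR,
#'   default 0.40), `lowpass_hz` (cutoff of the zero-phase filter applied
#'   before differentiation, default 25), `min_width_ms` (candidates
#'   narrower than this are noise, default 10), `min_voltage_uv` (minimum
#'   apex amplitude for a detection, default 100), the cleanup thresholds
#'   `merge_valley_frac` (0.90), `remove_diff_frac` (0.50),
#'   `horizontal_angle_deg` (5), and the offset cost weights `w1`, `w2`
#'   (0.5 each).
#' @param correction heart-rate correction: `qt_method`
#'   (`"fridericia_qt"`), `jtpeak_method` (`"jtpeak_power"`) and
#'   `jtpeak_exponent` (default 0.58).
#'
#' @return A classed nested list (`jt_config`).
#' @export
jt_config <- function(baseline = list(), qrs = list(), median = list(),
                      vm = list(), delineate = list(), correction = list()) {
  defaults <- list(
    baseline = list(knot_offset_ms = 80, knot_window_ms = 20),
    qrs = list(band_hz = c(5, 25), refractory_ms = 200, threshold_frac = 0.3,
               running_max_ms = 2000),
    median = list(pre_ms = 300, post_max_ms = 700, post_rr_frac = 0.9,
                  min_beats = 3),
    vm = list(transform_matrix = NULL),
    delineate = list(
      window_start_offset_ms = 25, window_rr_frac = 0.40,
      lowpass_hz = 25, min_width_ms = 10, min_voltage_uv = 100,
      merge_valley_frac = 0.90, remove_diff_frac = 0.50,
      horizontal_angle_deg = 5,
      w1 = 0.5, w2 = 0.5,
      min_energy_interval_ms = 5,
      baseline_level_uv = 0,
      tangent_search_ms = 300,
      min_tail_ms = 50
    ),
    correction = list(qt_method = "fridericia_qt",
                      jtpeak_method = "jtpeak_power",
                      jtpeak_exponent = 0.58)
  )
  user <- list(baseline = baseline, qrs = qrs, median = median, vm = vm,
               delineate = delineate, correction = correction)
  for (section in names(user)) {
    if (!is.list(user[[section]]))
      jt_stop("jt_config_error", sprintf("config section '%s' must be a list", section))
    unknown <- setdiff(names(user[[section]]), names(defaults[[section]]))
    if (length(unknown))
      jt_stop("jt_config_error",
              sprintf("unknown config key(s) in '%s': %s", section,
                      paste(unknown, collapse = ", ")))
    defaults[[section]] <- utils::modifyList(defaults[[section]], user[[section]])
  }
  structure(defaults, class = "jt_config")
}

as_jt_config <- function(config) {
  if (is.null(config)) return(jt_config())
  if (inherits(config, "jt_config")) return(config)
  if (is.list(config)) return(do.call(jt_config, config))
  jt_stop("jt_config_error", "config must be NULL, a jt_config, or a named list")
}
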