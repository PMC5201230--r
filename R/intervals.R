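# Interval computation and heart-rate correction.

#' Measure ECG intervals from a fiducial set
#'
#' Raw intervals: `QT = Tend - QRSonset`, `J-Tpeak = Tpeak - QRSoffset`,
#' `Tpeak-Tend = Tend - Tpeak` (so `QT = (QRSoffset - QRSonset) + J-Tpeak +
#' Tpeak-Tend` by construction).  QT and J-Tpeak are additionally
#' heart-rate corrected per the `correction` config; Tpeak-Tend is
#' reported uncorrected.
#'
#' @param fiducials a measurable [delineate_twave()] `fiducial_set` with
#'   QRS onset and offset present.
#' @param rr_ms RR interval in ms (> 0).
#' @param config a [jt_config()].
#' @return Object of class `interval_set`: `rr_ms`, `qt_ms`, `jtpeak_ms`,
#'   `tpeak_tend_ms`, `qtc_ms`, `jtpeakc_ms`, `correction_method`.
#' @export
measure_intervals <- function(fiducials, rr_ms, config = NULL) {
  config <- as_jt_config(config)
  cc <- config$correction
  f <- fiducials
  if (!isTRUE(f$measurable))
    jt_stop("jt_incomplete_measurement", "beat is flagged unmeasurable")
  need <- c("qrs_onset_ms", "qrs_offset_ms", "t_peak_ms", "t_end_ms")
  vals <- unlist(f[need])
  if (any(is.na(vals)))
    jt_stop("jt_incomplete_measurement",
            sprintf("missing fiducial(s): %s", paste(need[is.na(vals)], collapse = ", ")))
  if (rr_ms <= 0) jt_stop("jt_input_error", "rr_ms must be positive")
  qt <- f$t_end_ms - f$qrs_onset_ms
  jtp <- f$t_peak_ms - f$qrs_offset_ms
  tpte <- f$t_end_ms - f$t_peak_ms
  if (tpte <= 0) jt_stop("jt_incomplete_measurement", "zero-length Tpeak-Tend interval")
  if (qt <= 0 || jtp <= 0)
    jt_stop("jt_incomplete_measurement", "non-positive interval")
  structure(
    list(rr_ms = rr_ms, qt_ms = qt, jtpeak_ms = jtp, tpeak_tend_ms = tpte,
         qtc_ms = rate_correct(qt, rr_ms, cc$qt_method, config = config),
         jtpeakc_ms = rate_correct(jtp, rr_ms, cc$jtpeak_method, config = config),
         correction_method = sprintf("%s/%s(e=%g)", cc$qt_method,
                                     cc$jtpeak_method, cc$jtpeak_exponent)),
    class = "interval_set"
  )
}

#' Heart-rate correction of an interval
#'
#' `fridericia_qt`: interval / (RR/1000)^(1/3).  `jtpeak_power`:
#' interval / (RR/1000)^e with configurable exponent `e` (default 0.58).
#' Both are the identity at RR = 1000 ms.
#'
#' @param interval_ms raw interval (ms).
#' @param rr_ms RR interval (ms, > 0).
#' @param method `"fridericia_qt"` or `"jtpeak_power"`.
#' @param exponent power-law exponent for `jtpeak_power`; default taken
#'   from `config`.
#' @param config a [jt_config()].
#' @return Corrected interval (ms).
#' @export
rate_correct <- function(interval_ms, rr_ms,
                         method = c("fridericia_qt", "jtpeak_power"),
                         exponent = NULL, config = NULL) {
  config <- as_jt_config(config)
  if (any(rr_ms <= 0)) jt_stop("jt_input_error", "rr_ms must be positive")
  if (!is.character(method) || !method[1] %in% c("fridericia_qt", "jtpeak_power"))
    jt_stop("jt_config_error", sprintf("unknown correction method '%s'", method[1]))
  method <- method[1]
  if (is.null(exponent)) exponent <- config$correction$jtpeak_exponent
  e <- switch(method, fridericia_qt = 1 / 3, jtpeak_power = exponent)
  interval_ms / (rr_ms / 1000)^e
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set> RR %.0f | QT %.1f (QTc %.1f) | J-Tpeak %.1f (c %.1f) | Tpeak-Tend %.1f ms\n",
              x$rr_ms, x$qt_ms, x$qtc_ms, x$jtpeak_ms, x$jtpeakc_ms, x$tpeak_tend_ms))
  invisible(x)
}
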