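# Geometric features of a (peak, trailing slur) candidate pair.
#
# Conventions: time in ms, amplitude in uV, angles via the inverse tangent
# in degrees (features are scale-dependent, so units are fixed).  Limb
# slopes come from least-squares fits between the bounding derivative
# extremum and the apex (instantaneous derivative where that segment is
# degenerate, see limb_line()).

#' Compute slur features for a peak/slur candidate pair
#'
#' Computes the 20 development features of a trailing slur relative to its
#' preceding peak: amplitude and time ratios between peak, slur and their
#' junction, limb angles and rotation angles.  The junction (`junction_x`)
#' is the intersection of the peak's falling limb line with the slur's
#' rising limb line (geometrically the "valley" between them); `y_origin`
#' of a candidate is the amplitude where the bisector of its two limb
#' lines, dropped from their intersection, crosses the signal.  Three of
#' the features drive the relevance classifier: `slur_limb_angle`,
#' `peak_slur_angle` and `amp_ratio_peak_slur`.
#'
#' @param peak,slur rows of a [find_candidates()] data.frame; the slur
#'   must follow the peak.
#' @param vm the `vm_beat` the candidates came from.
#' @param deriv optional precomputed [smooth_derivative()].
#' @param config a [jt_config()] (supplies `min_voltage_uv` for the
#'   divisor features).
#' @return A one-row data.frame of class `slur_features`.
#' @export
compute_slur_features <- function(peak, slur, vm, deriv = NULL, config = NULL) {
  stopifnot(inherits(vm, "vm_beat"))
  config <- as_jt_config(config)
  deriv <- as_vm_derivative(vm, deriv, config)
  if (slur$apex_ms < peak$apex_ms)
    jt_stop("jt_input_error", "slur must follow the peak")
  if (slur$fall_ms <= slur$rise_ms || peak$fall_ms <= peak$rise_ms)
    jt_stop("jt_feature_error", "zero-length candidate")

  pl <- candidate_limbs(peak, deriv)
  sl <- candidate_limbs(slur, deriv)
  ang <- list(p_rising = atand(pl$rising[2]), p_falling = atand(pl$falling[2]),
              s_rising = atand(sl$rising[2]), s_falling = atand(sl$falling[2]))

  junction <- line_intersection(pl$falling, sl$rising)
  if (is.null(junction))
    jt_stop("jt_feature_error", "parallel limb lines: no junction")
  jx <- junction[["x"]]
  if (jx < peak$apex_ms || jx > slur$fall_ms + 50)
    jt_stop("jt_feature_error", "junction outside the peak-slur span")
  y_junction <- signal_at(deriv, jx)

  y_p <- peak$apex_uv; y_s <- slur$apex_uv
  x_p <- peak$apex_ms; x_s <- slur$apex_ms
  min_voltage <- config$delineate$min_voltage_uv
  divisor <- abs(y_junction - min_voltage)
  yorigin_p <- bisector_origin(pl, deriv)
  yorigin_s <- bisector_origin(sl, deriv)
  rotation_p <- 90 - (ang$p_rising + ang$p_falling) / 2
  rotation_s <- 90 - (ang$s_rising + ang$s_falling) / 2
  ratio_or_na <- function(a, b) if (is.na(b) || abs(b) < 1e-9) NA_real_ else a / b

  out <- data.frame(
    amp_ratio_peak_slur = y_p / y_s,
    amp_ratio_peak_slur_origin = ratio_or_na(y_p, yorigin_s),
    amp_ratio_origin = ratio_or_na(yorigin_p, yorigin_s),
    time_ratio_peak_slur = x_p / x_s,
    amp_diff_peak_slur = y_p - y_s,
    amp_diff_junction_peak = abs(y_junction - y_p),
    amp_diff_junction_slur = abs(y_junction - y_s),
    amp_ratio_junction_peak = abs(y_junction / y_p),
    amp_ratio_junction_slur = abs(y_junction / y_s),
    time_ratio_peak_junction = x_p / jx,
    time_ratio_slur_junction = x_s / jx,
    time_ratio_rel = abs(x_p - jx) / abs(x_s - jx),
    amp_ratio_rel = abs(y_p - y_junction) / abs(y_s - y_junction),
    amp_ratio_peak_divisor = ratio_or_na(y_p - min_voltage, divisor),
    amp_ratio_slur_divisor = ratio_or_na(y_s - min_voltage, divisor),
    peak_limb_angle = abs(ang$p_rising - ang$p_falling),
    slur_limb_angle = abs(ang$s_rising - ang$s_falling),
    peak_slur_angle = abs(ang$p_falling - ang$s_rising),
    peak_rotation = atand(rotation_p),
    slur_rotation = atand(rotation_s),
    stringsAsFactors = FALSE
  )
  class(out) <- c("slur_features", "data.frame")
  out
}

# Smoothed-signal amplitude at an arbitrary (fractional) time, by linear
# interpolation; clamped to the beat.
signal_at <- function(deriv, t_ms) {
  n <- length(deriv$smoothed)
  t <- min(max(t_ms, 0), index_to_ms(n, deriv$fs))
  i <- floor(t) + 1
  if (i >= n) return(deriv$smoothed[n])
  frac <- t - (i - 1)
  deriv$smoothed[i] * (1 - frac) + deriv$smoothed[i + 1] * frac
}

# Amplitude where the bisector of a candidate's two limb lines, dropped
# from the limb-line intersection, crosses the smoothed signal.  NA when
# the geometry is degenerate or no crossing is found nearby.
bisector_origin <- function(limbs, deriv, max_reach = 1500) {
  apexish <- line_intersection(limbs$rising, limbs$falling)
  if (is.null(apexish)) return(NA_real_)
  phi <- (atan(limbs$rising[2]) + atan(limbs$falling[2])) / 2 - pi / 2
  dx <- cos(phi); dy <- sin(phi)
  g <- function(t) {
    x <- apexish[["x"]] + t * dx
    (apexish[["y"]] + t * dy) - signal_at(deriv, x)
  }
  ts <- seq(0, max_reach, by = 2)
  vals <- vapply(ts, g, numeric(1))
  cross <- which(vals[-1] * vals[-length(vals)] <= 0)
  if (!length(cross)) return(NA_real_)
  k <- cross[1]
  root <- tryCatch(stats::uniroot(g, c(ts[k], ts[k + 1]))$root,
                   error = function(e) NA_real_)
  if (is.na(root)) return(NA_real_)
  signal_at(deriv, apexish[["x"]] + root * dx)
}
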