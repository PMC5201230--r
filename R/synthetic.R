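# Synthetic median beats and 10 s ECG segments with analytic ground truth.
#
# Waveforms are sums of Gaussian bumps (a triphasic Gaussian set for the
# QRS, one to two Gaussians for the T-wave), generated in orthogonal XYZ
# space along a fixed unit direction so the noiseless vector magnitude
# equals the scalar waveform exactly.  Ground-truth fiducials are derived
# analytically/numerically from the component list, never from the
# delineator: the T-peak is the dense-grid argmax of the noiseless T-wave
# and the T-end is the closed-form tangent offset of the terminal
# Gaussian, center + 2*width.

QRS_TEMPLATE <- data.frame(       # trigger-relative, ms / uV
  amp_uv = c(-80, 900, -120),
  center_ms = c(-8, 0, 12),
  width_ms = c(4, 7, 5)
)
QRS_ONSET_REL <- -22              # QRS onset relative to the trigger (ms)
QRS_OFFSET_REL <- 30              # J-point relative to the trigger (ms)

# default T-wave morphologies (beat coordinates, alignment at 100 ms)
default_t_components <- function(morphology, alignment_ms = 100) {
  shift <- alignment_ms - 100
  comps <- switch(morphology,
    normal = data.frame(amp_uv = 400, center_ms = 340, width_ms = 30),
    flat = data.frame(amp_uv = 120, center_ms = 340, width_ms = 45),
    notched = data.frame(amp_uv = c(350, 420), center_ms = c(300, 365),
                         width_ms = c(20, 22)),
    slurred = data.frame(amp_uv = c(400, 140), center_ms = c(340, 285),
                         width_ms = c(30, 18)),
    jt_stop("jt_spec_error", sprintf("unknown morphology '%s'", morphology))
  )
  comps$center_ms <- comps$center_ms + shift
  comps
}

#' Specification of a synthetic beat
#'
#' Describes one beat: T-wave morphology class, Gaussian T components,
#' RR interval, additive white noise level, baseline wander and seed.
#' Morphology invariants are enforced: `normal` has one T component,
#' `notched` two with center separation greater than twice the smaller
#' width, `flat` a peak amplitude of at most 150 uV, and `slurred` a
#' shoulder component smaller than the main one.
#'
#' @param morphology one of `"normal"`, `"flat"`, `"notched"`,
#'   `"slurred"`.
#' @param t_components data.frame with columns `amp_uv`, `center_ms`,
#'   `width_ms` (beat coordinates); `NULL` for the morphology default.
#' @param rr_ms RR interval (ms).
#' @param noise_sd_uv white-noise standard deviation per orthogonal lead.
#' @param wander_amp_uv,wander_freq_hz sinusoidal baseline wander (applied
#'   by [generate_record()] only; a median beat is wander-free by
#'   construction).
#' @param seed integer RNG seed; the same spec always generates the same
#'   samples.
#' @param alignment_ms QRS trigger time within the beat.
#' @param beat_length_ms beat length; default `alignment_ms + 0.75 * rr_ms`.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(morphology = c("normal", "flat", "notched", "slurred"),
                           t_components = NULL, rr_ms = 1000, noise_sd_uv = 0,
                           wander_amp_uv = 0, wander_freq_hz = 0.3, seed = 1,
                           alignment_ms = 100, beat_length_ms = NULL) {
  morphology <- match.arg(morphology)
  if (is.null(t_components)) t_components <- default_t_components(morphology, alignment_ms)
  t_components <- as.data.frame(t_components)
  stopifnot(all(c("amp_uv", "center_ms", "width_ms") %in% names(t_components)))
  if (any(t_components$width_ms <= 0) || any(t_components$amp_uv <= 0))
    jt_stop("jt_spec_error", "T components need positive amplitude and width")
  if (morphology == "normal" && nrow(t_components) != 1)
    jt_stop("jt_spec_error", "normal morphology has exactly one T component")
  if (morphology == "notched") {
    if (nrow(t_components) != 2)
      jt_stop("jt_spec_error", "notched morphology has exactly two T components")
    sep <- abs(diff(t_components$center_ms))
    if (sep <= 2 * min(t_components$width_ms))
      jt_stop("jt_spec_error", "notch separation must exceed twice the minimum width")
  }
  if (morphology == "flat" && max(t_components$amp_uv) > 150)
    jt_stop("jt_spec_error", "flat morphology: peak amplitude must be <= 150 uV")
  if (morphology == "slurred") {
    if (nrow(t_components) < 2)
      jt_stop("jt_spec_error", "slurred morphology needs a shoulder component")
    if (min(t_components$amp_uv) >= max(t_components$amp_uv))
      jt_stop("jt_spec_error", "slur shoulder must be smaller than the main component")
  }
  if (is.null(beat_length_ms)) beat_length_ms <- round(alignment_ms + 0.75 * rr_ms)
  structure(
    list(morphology = morphology, t_components = t_components, rr_ms = rr_ms,
         noise_sd_uv = noise_sd_uv, wander_amp_uv = wander_amp_uv,
         wander_freq_hz = wander_freq_hz, seed = as.integer(seed),
         alignment_ms = alignment_ms, beat_length_ms = beat_length_ms),
    class = "synthetic_spec"
  )
}

gaussian_sum <- function(t_ms, comps) {
  s <- numeric(length(t_ms))
  for (k in seq_len(nrow(comps)))
    s <- s + comps$amp_uv[k] * exp(-0.5 * ((t_ms - comps$center_ms[k]) / comps$width_ms[k])^2)
  s
}

gaussian_sum_deriv <- function(t_ms, comps) {
  d <- numeric(length(t_ms))
  for (k in seq_len(nrow(comps))) {
    z <- (t_ms - comps$center_ms[k]) / comps$width_ms[k]
    d <- d - comps$amp_uv[k] * z / comps$width_ms[k] * exp(-0.5 * z^2)
  }
  d
}

# orthogonal direction of the synthetic dipole (unit vector) and the
# least-norm 8-lead loading that maps back to it through the bundled
# transform, so transform_xyz() reproduces the XYZ signal exactly.
XYZ_DIRECTION <- c(x = 2 / 3, y = 2 / 3, z = 1 / 3)

lead_loadings <- function(m = default_xyz_matrix()) {
  pinv <- t(m) %*% solve(m %*% t(m))
  as.numeric(pinv %*% XYZ_DIRECTION)
}

#' Dense-grid tangent T-end of a Gaussian T-wave
#'
#' Independent numeric computation of the tangent-method offset for a sum
#' of Gaussian components using the analytic derivative on a 0.01 ms
#' grid: steepest descending slope after `from_ms`, tangent intersected
#' with zero.  Used for ground-truth validation and corpus labelling.
#'
#' @param comps data.frame `amp_uv`, `center_ms`, `width_ms`.
#' @param from_ms search start (default: after the latest component
#'   center).
#' @return Tangent offset time (ms).
#' @export
dense_tangent_tend <- function(comps, from_ms = NULL) {
  if (is.null(from_ms)) from_ms <- max(comps$center_ms)
  terminal <- comps$center_ms + 4 * comps$width_ms
  grid <- seq(from_ms, max(terminal), by = 0.01)
  d <- gaussian_sum_deriv(grid, comps)
  i <- which.min(d)
  grid[i] - gaussian_sum(grid[i], comps) / d[i]
}

ground_truth_from_components <- function(comps, alignment_ms) {
  lo <- min(comps$center_ms - 3 * comps$width_ms)
  hi <- max(comps$center_ms + 3 * comps$width_ms)
  grid <- seq(lo, hi, by = 0.02)
  s <- gaussian_sum(grid, comps)
  t_peak <- grid[which.max(s)]
  # local maxima of the noiseless T-wave on the dense grid
  imax <- local_maxima(s)
  notched <- length(imax) >= 2
  secondary <- NA_real_
  if (notched) {
    tops <- grid[imax][order(s[imax], decreasing = TRUE)]
    secondary <- tops[which(abs(tops - t_peak) > 1e-6)[1]]
  }
  terminal <- which.max(comps$center_ms)
  structure(
    list(qrs_onset_ms = alignment_ms + QRS_ONSET_REL,
         qrs_offset_ms = alignment_ms + QRS_OFFSET_REL,
         t_peak_true_ms = t_peak,
         secondary_peak_true_ms = secondary,
         t_end_true_ms = comps$center_ms[terminal] + 2 * comps$width_ms[terminal],
         notched = notched),
    class = "ground_truth"
  )
}

#' Generate one synthetic beat with ground truth
#'
#' Deterministic for a fixed spec (the seed is part of the spec).  The
#' noiseless waveform is the QRS template plus the spec's T components,
#' emitted along a fixed orthogonal direction; white noise is added per
#' orthogonal (or per derived) lead.
#'
#' @param spec a [synthetic_spec()].
#' @param output `"vm"` (vector magnitude beat), `"xyz"`, or `"median"`
#'   (8-lead median beat whose [transform_xyz()] reproduces the XYZ
#'   signal).
#' @return List with `beat` (a `vm_beat`, `xyz_beat` or `median_beat`),
#'   `truth` (a `ground_truth`) and `spec`.
#' @export
generate_beat <- function(spec, output = c("vm", "xyz", "median")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  output <- match.arg(output)
  t <- seq(0, spec$beat_length_ms - 1)
  qrs <- QRS_TEMPLATE
  qrs$center_ms <- qrs$center_ms + spec$alignment_ms
  s <- gaussian_sum(t, rbind(qrs, spec$t_components))
  truth <- ground_truth_from_components(spec$t_components, spec$alignment_ms)
  set.seed(spec$seed)
  if (output == "median") {
    w8 <- lead_loadings()
    leads <- outer(s, w8)
    if (spec$noise_sd_uv > 0)
      leads <- leads + matrix(stats::rnorm(length(leads), sd = spec$noise_sd_uv),
                              nrow = nrow(leads))
    colnames(leads) <- REQUIRED_LEADS
    beat <- new_median_beat(leads, alignment_ms = spec$alignment_ms,
                            median_rr_ms = spec$rr_ms, n_beats_used = NA_integer_)
    return(list(beat = beat, truth = truth, spec = spec))
  }
  noise <- function() if (spec$noise_sd_uv > 0)
    stats::rnorm(length(t), sd = spec$noise_sd_uv) else 0
  x <- s * XYZ_DIRECTION[1] + noise()
  y <- s * XYZ_DIRECTION[2] + noise()
  z <- s * XYZ_DIRECTION[3] + noise()
  xyz <- structure(list(x = x, y = y, z = z, fs = 1000,
                        alignment_ms = spec$alignment_ms,
                        median_rr_ms = spec$rr_ms),
                   class = "xyz_beat")
  if (output == "xyz") return(list(beat = xyz, truth = truth, spec = spec))
  list(beat = vector_magnitude(xyz), truth = truth, spec = spec)
}

#' Generate a 10 s multi-lead ECG segment with ground truth
#'
#' Repeats the spec's beat at a regular RR, emits 8 leads at the given
#' sampling rate, adds per-lead white noise and sinusoidal baseline
#' wander (random phase per lead), and quantizes amplitudes to a 2.5 uV
#' resolution.  Ground truth is returned both trigger-relative and in the
#' coordinates of the median beat that [build_median_beat()] produces.
#'
#' @param spec a [synthetic_spec()].
#' @param duration_s segment length in seconds (default 10).
#' @param fs sampling rate in Hz (default 500).
#' @param first_trigger_ms time of the first QRS trigger.
#' @param median_pre_ms `pre_ms` of the median-beat window the
#'   beat-coordinate truth refers to (default 300).
#' @return List with `record` (an `ecg_record`), `truth`
#'   (`trigger_ms`, trigger-relative fiducials) and `median_truth` (a
#'   `ground_truth` in median-beat coordinates).
#' @export
generate_record <- function(spec, duration_s = 10, fs = 500,
                            first_trigger_ms = 400, median_pre_ms = 300) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dur_ms <- duration_s * 1000
  triggers_ms <- seq(first_trigger_ms, dur_ms - 600, by = spec$rr_ms)
  n <- as.integer(duration_s * fs)
  t <- (seq_len(n) - 1) * 1000 / fs
  t_rel <- spec$t_components
  t_rel$center_ms <- t_rel$center_ms - spec$alignment_ms   # trigger-relative
  comps <- do.call(rbind, lapply(triggers_ms, function(tr) {
    beat <- rbind(QRS_TEMPLATE, t_rel)
    beat$center_ms <- beat$center_ms + tr
    beat
  }))
  s <- gaussian_sum(t, comps)
  w8 <- lead_loadings()
  leads <- outer(s, w8)
  set.seed(spec$seed)
  if (spec$noise_sd_uv > 0)
    leads <- leads + matrix(stats::rnorm(length(leads), sd = spec$noise_sd_uv),
                            nrow = n)
  if (spec$wander_amp_uv > 0) {
    phases <- stats::runif(ncol(leads), 0, 2 * pi)
    for (lead in seq_len(ncol(leads)))
      leads[, lead] <- leads[, lead] +
        spec$wander_amp_uv * sin(2 * pi * spec$wander_freq_hz * t / 1000 + phases[lead])
  }
  leads <- round(leads / 2.5) * 2.5   # 2.5 uV amplitude resolution
  colnames(leads) <- REQUIRED_LEADS
  record <- new_ecg_record(leads, fs = fs, lead_names = REQUIRED_LEADS)
  beat_truth <- ground_truth_from_components(spec$t_components, spec$alignment_ms)
  shift <- median_pre_ms - spec$alignment_ms
  median_truth <- beat_truth
  for (f in c("qrs_onset_ms", "qrs_offset_ms", "t_peak_true_ms",
              "secondary_peak_true_ms", "t_end_true_ms"))
    median_truth[[f]] <- median_truth[[f]] + shift
  list(record = record,
       truth = list(trigger_ms = triggers_ms,
                    qrs_onset_rel_ms = QRS_ONSET_REL,
                    qrs_offset_rel_ms = QRS_OFFSET_REL,
                    beat_truth = beat_truth),
       median_truth = median_truth)
}

#' Generate a synthetic study corpus
#'
#' Emulates a crossover-trial ECG corpus: `n_subjects` subjects with
#' subject-specific T-wave geometry (amplitude, width, timing drawn once
#' per subject), `n_timepoints` time points whose T-wave timing is
#' shifted by `effect_profile` (a drug-effect emulation), and
#' `n_replicates` replicate beats per time point sharing morphology but
#' with independent noise.  Fully seeded and reproducible.
#'
#' @param n_subjects,n_timepoints,n_replicates corpus dimensions (all
#'   >= 1).
#' @param effect_profile numeric vector of per-time-point T-wave shifts in
#'   ms (recycled to `n_timepoints`; default all zero).
#' @param morphology morphology class for all subjects, or a vector to
#'   sample from per subject.
#' @param noise_sd_uv per-lead white-noise SD (default 5).
#' @param rr_ms nominal RR; each subject gets a fixed jitter of up to
#'   +/-100 ms.
#' @param seed master seed.
#' @return List of class `synthetic_study`: `entries` (one element per
#'   beat: `subject`, `timepoint`, `replicate`, `beat` (a `vm_beat`),
#'   `truth`), plus the generation parameters.
#' @export
generate_study <- function(n_subjects = 22, n_timepoints = 8, n_replicates = 3,
                           effect_profile = NULL, morphology = "normal",
                           noise_sd_uv = 5, rr_ms = 1000, seed = 1) {
  stopifnot(n_subjects >= 1, n_timepoints >= 1, n_replicates >= 1)
  if (is.null(effect_profile)) effect_profile <- numeric(n_timepoints)
  effect_profile <- rep_len(effect_profile, n_timepoints)
  set.seed(seed)
  subj_morph <- sample(rep_len(morphology, n_subjects))
  amp_scale <- stats::runif(n_subjects, 0.85, 1.15)
  width_scale <- stats::runif(n_subjects, 0.9, 1.1)
  center_shift <- stats::runif(n_subjects, -15, 15)
  rr_subj <- rr_ms + round(stats::runif(n_subjects, -100, 100))
  seeds <- sample.int(.Machine$integer.max - 1L,
                      n_subjects * n_timepoints * n_replicates)
  entries <- vector("list", length(seeds))
  k <- 0L
  for (subj in seq_len(n_subjects)) {
    base <- default_t_components(subj_morph[subj])
    base$amp_uv <- base$amp_uv * amp_scale[subj]
    base$width_ms <- base$width_ms * width_scale[subj]
    base$center_ms <- base$center_ms + center_shift[subj]
    for (tp in seq_len(n_timepoints)) {
      comps <- base
      comps$center_ms <- comps$center_ms + effect_profile[tp]
      for (rep_i in seq_len(n_replicates)) {
        k <- k + 1L
        spec <- synthetic_spec(subj_morph[subj], t_components = comps,
                               rr_ms = rr_subj[subj], noise_sd_uv = noise_sd_uv,
                               seed = seeds[k])
        gen <- generate_beat(spec, output = "vm")
        entries[[k]] <- list(subject = subj, timepoint = tp, replicate = rep_i,
                             beat = gen$beat, truth = gen$truth)
      }
    }
  }
  structure(
    list(entries = entries, n_subjects = n_subjects,
         n_timepoints = n_timepoints, n_replicates = n_replicates,
         effect_profile = effect_profile, morphology = morphology,
         noise_sd_uv = noise_sd_uv, seed = seed),
    class = "synthetic_study"
  )
}

#' Labeled slur corpus for relevance-tree training
#'
#' Generates noiseless beats with a main T-wave Gaussian plus a trailing
#' deflection, runs candidate detection and cleanup, and keeps the (last
#' peak, first trailing slur) pairs.  Two sub-populations are drawn with
#' equal probability: genuine late-repolarization shoulders (part of the
#' T-wave, fairly close to the peak and of comparable width), and
#' distractors -- wide shallow shelves far down the tail that emulate
#' non-repolarization activity (the extreme-flattening scenario).  The
#' label is derived from the generator truth, independent of the
#' classifier: a genuine shoulder is `relevant` when anchoring the
#' tangent after it moves the dense-grid tangent offset by more than 8 ms
#' relative to the main component alone (ignoring it would materially
#' truncate the measured T-wave); borderline shoulders and all
#' distractors are `irrelevant`.
#'
#' @param n number of labeled examples to produce.
#' @param seed RNG seed.
#' @param config a [jt_config()].
#' @return data.frame: the [compute_slur_features()] columns, `label`, and
#'   the underlying `tend_shift_ms`.
#' @export
make_slur_corpus <- function(n = 500, seed = 7, config = NULL) {
  config <- as_jt_config(config)
  set.seed(seed)
  rows <- vector("list", n)
  collected <- 0L
  attempts <- 0L
  while (collected < n && attempts < 60L * n) {
    attempts <- attempts + 1L
    a_p <- stats::runif(1, 250, 500)
    mu_p <- stats::runif(1, 300, 360)
    sg_p <- stats::runif(1, 20, 32)
    genuine <- stats::runif(1) < 0.5
    if (genuine) {
      # adjacent shoulder of repolarization-like width
      a_s <- stats::runif(1, 0.15, 0.60) * a_p
      gap <- stats::runif(1, 1.1, 2.2) * sg_p
      sg_s <- stats::runif(1, 12, 28)
    } else {
      # broad shallow shelf well past the T limb (U-wave-like activity)
      a_s <- stats::runif(1, 100, 200)
      gap <- stats::runif(1, 2.6, 3.6) * sg_p
      sg_s <- stats::runif(1, 36, 60)
    }
    comps <- data.frame(amp_uv = c(a_p, a_s),
                        center_ms = c(mu_p, mu_p + gap),
                        width_ms = c(sg_p, sg_s))
    spec <- try(synthetic_spec("slurred", t_components = comps,
                               seed = attempts), silent = TRUE)
    if (inherits(spec, "try-error")) next
    gen <- generate_beat(spec, output = "vm")
    vmb <- gen$beat
    window <- tryCatch(
      define_search_window(gen$truth$qrs_offset_ms, vmb$alignment_ms,
                           vmb$median_rr_ms, config),
      jt_degenerate_window = function(e) NULL)
    if (is.null(window)) next
    deriv <- smooth_derivative(vmb, config)
    cands <- find_candidates(vmb, window, deriv, config)
    if (nrow(cands) < 2) next
    cands <- apply_cleanup_rules(cands, deriv, config)
    peak_rows <- which(cands$label == "peak")
    if (!length(peak_rows)) next
    lp <- peak_rows[length(peak_rows)]
    trailing <- which(cands$label == "slur" & seq_len(nrow(cands)) > lp)
    if (!length(trailing)) next
    feats <- tryCatch(
      compute_slur_features(cands[lp, ], cands[trailing[1], ], vmb, deriv, config),
      jt_feature_error = function(e) NULL, jt_input_error = function(e) NULL)
    if (is.null(feats)) next
    tend_full <- dense_tangent_tend(comps, from_ms = mu_p + gap)
    tend_main <- mu_p + 2 * sg_p
    shift <- tend_full - tend_main
    feats$tend_shift_ms <- shift
    feats$label <- if (genuine && shift > 8) "relevant" else "irrelevant"
    collected <- collected + 1L
    rows[[collected]] <- feats
  }
  if (collected < n)
    warning(sprintf("collected only %d of %d requested slur examples", collected, n))
  out <- do.call(rbind, rows[seq_len(collected)])
  rownames(out) <- NULL
  out
}
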