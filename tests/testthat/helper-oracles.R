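# Independent oracles used to cross-check the implementation.  These are
# deliberately naive (explicit loops, dense grids) and share no code with
# the package internals they verify.

# Naive candidate enumeration: scan the derivative for strict local
# extrema with a for-loop, pair each maximum with the first following
# minimum, then apply the width / amplitude / window retention rules.
oracle_candidates <- function(d, sm, window, fs = 1000,
                              min_width = 10, min_voltage = 100,
                              extension_ms = 150) {
  n <- length(d)
  lo <- max(2, round(window$start_ms * fs / 1000) + 1)
  hi <- min(n - 1, round(window$end_ms * fs / 1000) + 1 + extension_ms)
  # extrema strictly interior to the searched segment (same contract as
  # the implementation; computed here by explicit loop)
  maxima <- c(); minima <- c()
  for (i in (lo + 1):(hi - 1)) {
    if (d[i] > d[i - 1] && d[i] > d[i + 1]) maxima <- c(maxima, i)
    if (d[i] < d[i - 1] && d[i] < d[i + 1]) minima <- c(minima, i)
  }
  out <- NULL
  for (m in maxima) {
    fol <- minima[minima > m]
    if (length(fol) == 0) next
    f <- fol[1]
    apex <- m
    for (j in m:f) if (sm[j] > sm[apex]) apex <- j
    rise_ms <- (m - 1) * 1000 / fs; fall_ms <- (f - 1) * 1000 / fs
    apex_ms <- (apex - 1) * 1000 / fs
    if (fall_ms - rise_ms < min_width) next
    if (sm[apex] < min_voltage) next
    if (rise_ms < window$start_ms || rise_ms >= window$end_ms) next
    if (apex_ms >= window$end_ms) next
    lab <- if (max(d[m:f]) > 0 && min(d[m:f]) < 0) "peak" else "slur"
    out <- rbind(out, data.frame(rise_ms = rise_ms, fall_ms = fall_ms,
                                 apex_ms = apex_ms, label = lab))
  }
  out
}

# Dense-grid tangent search on a sampled signal: spline-interpolate the
# signal, locate the steepest descending slope after `after_ms` on a
# 0.05 ms grid by finite differences, intersect the tangent with zero.
oracle_tangent <- function(sm, after_ms, search_ms = 300, fs = 1000) {
  t <- (seq_along(sm) - 1) * 1000 / fs
  f <- stats::splinefun(t, sm, method = "fmm")
  grid <- seq(after_ms + 1, min(max(t), after_ms + search_ms), by = 0.05)
  h <- 0.05
  slopes <- (f(grid + h) - f(grid - h)) / (2 * h)
  i <- which.min(slopes)
  grid[i] - f(grid[i]) / slopes[i]
}

# Exhaustive cost evaluation for offset refinement.
oracle_refine <- function(minima_ms, e_values, tangent_ms, t_peak_ms,
                          next_qrs_ms, w1 = 0.5, w2 = 0.5) {
  cands <- c(minima_ms, tangent_ms)
  evals <- c(e_values, 0)
  cost <- w1 * (cands - t_peak_ms) / (next_qrs_ms - t_peak_ms) + w2 * evals
  ord <- order(cands)
  cands <- cands[ord]; cost <- cost[ord]
  cands[which(cost <= min(cost) + 1e-12)[1]]
}

# Random band-limited nonnegative test signal (sum of low-frequency
# sinusoids on a pedestal), for property tests over many waveforms.
random_band_limited_vm <- function(len_ms = 850, seed = 1, n_comp = 5,
                                   max_freq_hz = 8, pedestal = 400) {
  set.seed(seed)
  t <- seq(0, len_ms - 1)
  s <- rep(pedestal, length(t))
  for (k in seq_len(n_comp)) {
    a <- stats::runif(1, 20, 180)
    f <- stats::runif(1, 0.5, max_freq_hz)
    ph <- stats::runif(1, 0, 2 * pi)
    s <- s + a * sin(2 * pi * f * t / 1000 + ph)
  }
  s <- pmax(s, 0)
  new_vm_beat(s, alignment_ms = 100, median_rr_ms = 1000)
}

# A crafted derivative object (smoothed signal + central differences) for
# tests that need exact piecewise-linear geometry.
crafted_deriv <- function(sm, fs = 1000) {
  n <- length(sm)
  d <- numeric(n)
  d[2:(n - 1)] <- (sm[3:n] - sm[1:(n - 2)]) / 2
  d[1] <- sm[2] - sm[1]; d[n] <- sm[n] - sm[n - 1]
  structure(list(smoothed = sm, deriv = d, fs = fs), class = "vm_derivative")
}

make_candidate <- function(rise_ms, fall_ms, apex_ms, apex_uv, label) {
  out <- data.frame(rise_ms = rise_ms, fall_ms = fall_ms, apex_ms = apex_ms,
                    apex_uv = apex_uv, width_ms = fall_ms - rise_ms,
                    label = label, stringsAsFactors = FALSE)
  class(out) <- c("jt_candidates", "data.frame")
  out
}

truth_annotations <- function(truth) {
  list(qrs_onset_ms = truth$qrs_onset_ms, qrs_offset_ms = truth$qrs_offset_ms)
}
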