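make_flat_record <- function(wander, fs = 500, dur_s = 10) {
  n <- fs * dur_s
  leads <- matrix(rep(wander, 8), ncol = 8)
  colnames(leads) <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")
  new_ecg_record(leads, fs = fs, lead_names = colnames(leads))
}

test_that("cubic-spline baseline removal suppresses 0.3 Hz wander to < 10 uV", {
  fs <- 500
  t <- (0:(fs * 10 - 1)) / fs
  wander <- 200 * sin(2 * pi * 0.3 * t + 0.7)
  rec <- make_flat_record(wander, fs)
  trig <- new_beat_triggers(seq(200, 4800, by = 300), fs)  # one knot per beat at 100 bpm
  out <- remove_baseline(rec, trig)
  interior <- 700:4300  # away from spline end effects
  expect_lt(max(out$samples[interior, 1]) - min(out$samples[interior, 1]), 10)
})

test_that("baseline removal is exact on null and constant inputs", {
  fs <- 500
  rec0 <- make_flat_record(rep(0, fs * 10), fs)
  trig <- new_beat_triggers(seq(200, 4800, by = 500), fs)
  expect_equal(remove_baseline(rec0, trig)$samples, rec0$samples)
  rec_c <- make_flat_record(rep(100, fs * 10), fs)
  out <- remove_baseline(rec_c, trig)
  knots <- trig$trigger_samples - round(0.08 * fs)
  expect_equal(max(abs(out$samples[knots, 1])), 0, tolerance = 1e-9)
  expect_lt(mean(abs(out$samples[knots, ])), 1)  # knot-point residual ~ 0
  expect_error(remove_baseline(rec_c, new_beat_triggers(c(300, 800), fs)),
               class = "jt_insufficient_beats_error")
})

test_that("the substitute QRS detector hits every R apex within 10 ms", {
  spec <- synthetic_spec("normal", seed = 5)
  gen <- generate_record(spec)
  trig <- detect_qrs_triggers(gen$record)
  expect_length(trig$trigger_samples, length(gen$truth$trigger_ms))
  expect_true(all(abs(trig$trigger_ms - gen$truth$trigger_ms) <= 10))
  expect_equal(trig$median_rr_ms, 1000, tolerance = 0.01)

  noisy <- generate_record(synthetic_spec("normal", noise_sd_uv = 20, seed = 5))
  trig_n <- detect_qrs_triggers(noisy$record)
  expect_length(trig_n$trigger_samples, length(trig$trigger_samples))

  expect_error(detect_qrs_triggers(make_flat_record(rep(0, 5000))),
               class = "jt_no_beats_error")
})

test_that("median beat reproduces identical beats and resists an artifact burst", {
  spec <- synthetic_spec("normal", seed = 2)
  gen <- generate_record(spec)
  trig <- detect_qrs_triggers(gen$record)
  beat <- build_median_beat(gen$record, trig)
  expect_s3_class(beat, "median_beat")
  expect_equal(beat$alignment_ms, 300)
  # 1 ms resolution exactly
  expect_equal(nrow(beat$samples), 1001)

  # compare against one clean upsampled beat
  one <- gen$record$samples[(trig$trigger_samples[3] - 150):(trig$trigger_samples[3] + 350), "I"]
  up <- stats::spline((0:500) * 2, one, xout = 0:1000, method = "fmm")$y
  expect_lt(max(abs(beat$samples[, "I"] - up)), 1)

  # a 500 uV artifact burst in one beat leaves the median untouched
  dirty <- gen$record
  burst <- trig$trigger_samples[5] + (60:80)
  dirty$samples[burst, ] <- dirty$samples[burst, ] + 500
  beat_dirty <- build_median_beat(dirty, trig)
  expect_lt(max(abs(beat_dirty$samples - beat$samples)), 1)

  expect_error(build_median_beat(gen$record, new_beat_triggers(c(2000, 3000), 500)),
               class = "jt_insufficient_beats_error")
})

test_that("median beat is invariant under permutation of the input beats", {
  # build two records holding the same 1 s beat segments in different order
  fs <- 500
  seg_len <- fs
  set.seed(31)
  amps <- stats::runif(8, 350, 450)
  segs <- lapply(amps, function(a) {
    spec <- synthetic_spec("normal",
                           t_components = data.frame(amp_uv = a, center_ms = 340,
                                                     width_ms = 30),
                           seed = round(a))
    gr <- generate_record(spec, duration_s = 1, first_trigger_ms = 300)
    gr$record$samples
  })
  build <- function(order_idx) {
    samples <- do.call(rbind, segs[order_idx])
    rec <- new_ecg_record(samples, fs = fs, lead_names = colnames(samples))
    trig <- new_beat_triggers(seq(150, by = seg_len, length.out = 8) + 1, fs)
    build_median_beat(rec, trig)
  }
  expect_equal(build(1:8)$samples, build(c(5, 2, 8, 1, 7, 3, 6, 4))$samples,
               tolerance = 1e-9)
})

test_that("upsampling preserves local-maximum timing within 1 ms", {
  for (center in c(339, 340.5, 342)) {
    spec <- synthetic_spec("normal",
                           t_components = data.frame(amp_uv = 400, center_ms = center,
                                                     width_ms = 30),
                           seed = 1)
    gen <- generate_record(spec)
    trig <- detect_qrs_triggers(gen$record)
    beat <- build_median_beat(gen$record, trig)
    vm <- vector_magnitude(transform_xyz(beat))
    twin <- 450:650
    apex_ms <- twin[which.max(vm$vm[twin + 1])]
    expect_lt(abs(apex_ms - (300 + center - 100)), 1 + 1e-9)
  }
})
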