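test_that("generator truth matches the closed forms", {
  g <- generate_beat(synthetic_spec("normal"))
  expect_equal(g$truth$t_peak_true_ms, 340, tolerance = 0.03)
  expect_equal(g$truth$t_end_true_ms, 400)     # center + 2 * width
  expect_false(g$truth$notched)
  expect_equal(g$truth$qrs_offset_ms, 130)

  n <- generate_beat(synthetic_spec("notched",
    t_components = data.frame(amp_uv = c(350, 420), center_ms = c(300, 360),
                              width_ms = c(20, 22))))
  expect_true(n$truth$notched)
  # dense-grid maxima shift slightly where the components overlap
  expect_lt(abs(n$truth$t_peak_true_ms - 360), 2)
  expect_lt(abs(n$truth$secondary_peak_true_ms - 300), 2)
  expect_equal(n$truth$t_end_true_ms, 360 + 44)
})

test_that("generation is deterministic for a fixed spec", {
  spec <- synthetic_spec("normal", noise_sd_uv = 8, seed = 99)
  b1 <- generate_beat(spec); b2 <- generate_beat(spec)
  expect_identical(b1$beat$vm, b2$beat$vm)
  r1 <- generate_record(spec); r2 <- generate_record(spec)
  expect_identical(r1$record$samples, r2$record$samples)
})

test_that("morphology invariants are enforced at spec construction", {
  expect_error(synthetic_spec("normal", t_components = data.frame(
    amp_uv = c(1, 1), center_ms = c(1, 2), width_ms = c(1, 1))),
    class = "jt_spec_error")
  expect_error(synthetic_spec("notched", t_components = data.frame(
    amp_uv = c(350, 420), center_ms = c(300, 330), width_ms = c(20, 22))),
    class = "jt_spec_error")  # separation below twice the minimum width
  expect_error(synthetic_spec("flat", t_components = data.frame(
    amp_uv = 300, center_ms = 340, width_ms = 45)), class = "jt_spec_error")
  expect_error(synthetic_spec("slurred", t_components = data.frame(
    amp_uv = 400, center_ms = 340, width_ms = 30)), class = "jt_spec_error")
})

test_that("closed-form T-end agrees with the dense-grid tangent within 0.5 ms", {
  specs <- list(
    synthetic_spec("normal"),
    synthetic_spec("flat"),
    synthetic_spec("notched"),
    synthetic_spec("slurred"),
    synthetic_spec("normal", t_components = data.frame(
      amp_uv = 300, center_ms = 360, width_ms = 55))
  )
  for (spec in specs) {
    comps <- spec$t_components
    terminal <- which.max(comps$center_ms)
    closed <- comps$center_ms[terminal] + 2 * comps$width_ms[terminal]
    dense <- dense_tangent_tend(comps)
    expect_lt(abs(closed - dense), 0.5)
  }
})

test_that("10 s records have the declared geometry and amplitude grid", {
  gr <- generate_record(synthetic_spec("normal", noise_sd_uv = 5, seed = 2))
  expect_equal(nrow(gr$record$samples), 5000)
  expect_equal(gr$record$fs, 500)
  expect_length(gr$truth$trigger_ms, 10)
  q <- gr$record$samples / 2.5
  expect_equal(q, round(q), tolerance = 1e-9)   # 2.5 uV resolution
  # median-beat coordinates of the truth: alignment moves from 100 to 300
  expect_equal(gr$median_truth$t_peak_true_ms,
               gr$truth$beat_truth$t_peak_true_ms + 200)
})

test_that("the 8-lead median output reproduces the XYZ signal through the transform", {
  g_vm <- generate_beat(synthetic_spec("slurred"))
  g_m8 <- generate_beat(synthetic_spec("slurred"), output = "median")
  vm8 <- vector_magnitude(transform_xyz(g_m8$beat))
  expect_equal(vm8$vm, g_vm$beat$vm, tolerance = 1e-6)
})

test_that("study corpora share truth within a time point and regenerate identically", {
  study <- generate_study(n_subjects = 3, n_timepoints = 2, n_replicates = 3,
                          noise_sd_uv = 5, seed = 123)
  expect_length(study$entries, 18)
  by_tp <- split(study$entries, vapply(study$entries, function(e)
    paste(e$subject, e$timepoint), character(1)))
  for (grp in by_tp) {
    truths <- vapply(grp, function(e) e$truth$t_peak_true_ms, numeric(1))
    expect_equal(max(truths) - min(truths), 0)
  }
  # zero effect profile: truth constant across time points within subject
  for (s in 1:3) {
    tr <- vapply(study$entries[vapply(study$entries, function(e) e$subject == s,
                                      logical(1))],
                 function(e) e$truth$t_end_true_ms, numeric(1))
    expect_equal(max(tr) - min(tr), 0)
  }
  study2 <- generate_study(n_subjects = 3, n_timepoints = 2, n_replicates = 3,
                           noise_sd_uv = 5, seed = 123)
  expect_identical(study$entries[[7]]$beat$vm, study2$entries[[7]]$beat$vm)

  # a nonzero effect shifts truth by exactly the profile
  shifted <- generate_study(n_subjects = 2, n_timepoints = 2, n_replicates = 1,
                            effect_profile = c(0, 20), seed = 5)
  for (s in 1:2) {
    es <- shifted$entries[vapply(shifted$entries, function(e) e$subject == s,
                                 logical(1))]
    tp <- vapply(es, function(e) e$timepoint, numeric(1))
    expect_equal(es[[which(tp == 2)]]$truth$t_end_true_ms -
                 es[[which(tp == 1)]]$truth$t_end_true_ms, 20)
  }
})
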