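test_that("systolic peak detection matches generator ground truth", {
  m <- gaussian_morph(center = 0.30)
  b <- generate_beat(m, fs = 120)
  beat <- make_beat(b$samples)
  peak <- detect_systolic_peak(beat)
  expect_lte(abs(peak$t - b$truth$t_sys), 1 / 120)
})

test_that("equal maxima break ties toward the earlier peak", {
  beat <- make_beat(c(0, 0.2, 1, 0.5, 1, 0.2, 0))
  peak <- detect_systolic_peak(beat)
  expect_equal(peak$t, 2 / 120)
})

test_that("boundary maxima are malformed beats", {
  expect_error(detect_systolic_peak(make_beat(seq(0, 1, length.out = 50))),
               class = "ppg_malformed_beat")
})

test_that("APG approximates the analytic second derivative of a sine", {
  fs <- 120
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  beat <- make_beat(sin(2 * pi * t), fs = fs)
  apg <- compute_apg(beat)
  expect_length(apg, length(t))
  truth <- -(2 * pi)^2 * sin(2 * pi * t)
  mid <- 30:90
  expect_lt(max(abs(apg[mid] - truth[mid])) / (2 * pi)^2, 0.05)
})

test_that("APG of a line is zero and APG is linear in the beat", {
  fs <- 120
  lin <- make_beat(seq(0, 1, length.out = 60), fs = fs)
  expect_lt(max(abs(compute_apg(lin))), 1e-8)
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  b1 <- make_beat(sin(2 * pi * t), fs = fs)
  b3 <- make_beat(3 * sin(2 * pi * t), fs = fs)
  expect_equal(compute_apg(b3), 3 * compute_apg(b1), tolerance = 1e-10)
})

test_that("short beats shrink the APG window with a warning", {
  beat <- make_beat(sin(seq(0, pi, length.out = 9)))
  expect_warning(apg <- compute_apg(beat), "shrunk")
  expect_length(apg, 9)
})

test_that("APG a/b/e waves have the canonical order and signs", {
  b <- generate_beat(beat_morphology(), fs = 120)
  fid <- beat_fiducials(make_beat(b$samples))
  expect_lt(fid$apg_a$t, fid$t_sys)
  expect_gt(fid$apg_a$amp, 0)
  expect_lt(fid$apg_b$amp, 0)
  expect_true(fid$apg_a$t < fid$apg_b$t && fid$apg_b$t <= fid$t_sys)
  expect_false(is.null(fid$apg_e))
  expect_gt(fid$apg_e$t, fid$t_sys)
})

test_that("systolic-only beats have no e wave and no notch", {
  b <- generate_beat(gaussian_morph(), fs = 120)
  fid <- beat_fiducials(make_beat(b$samples))
  expect_null(fid$apg_e)
  expect_true(is.na(fid$t_notch))
  expect_equal(fid$notch_source, "absent")
})

test_that("notch detection matches the analytic inter-component minimum", {
  m <- beat_morphology()
  b <- generate_beat(m, fs = 120)
  fid <- beat_fiducials(make_beat(b$samples))
  expect_equal(fid$notch_source, "derivative-minimum")
  expect_lte(abs(fid$t_notch - b$truth$t_notch), 2 / 120)
})

test_that("shoulder beats fall back to the APG e wave", {
  m <- beat_morphology(systolic_amp = 1, systolic_center = 0.30,
                       systolic_width = 0.09, diastolic_amp = 0.25,
                       diastolic_center = 0.52, diastolic_width = 0.13,
                       beat_period = 0.95)
  b <- generate_beat(m, fs = 120)
  # the fixture really is a shoulder: no local minimum after the peak
  tt <- seq(0, m$beat_period, length.out = 1e5)
  yy <- ppgscreen:::eval_beat(m, tt)
  expect_true(all(diff(yy[which.max(yy):length(yy)]) < 1e-9))
  fid <- beat_fiducials(make_beat(b$samples))
  expect_equal(fid$notch_source, "apg-e-wave")
  expect_true(fid$t_sys < fid$t_notch && fid$t_notch < fid$t_end)
})

test_that("fiducial ordering invariant holds across random morphologies", {
  set.seed(404)
  for (i in 1:20) {
    m <- random_morphology()
    b <- generate_beat(m, fs = 120)
    fid <- tryCatch(beat_fiducials(make_beat(b$samples)),
                    ppg_error = function(e) NULL)
    if (is.null(fid)) next
    expect_lt(fid$t_onset, fid$t_sys)
    expect_lt(fid$t_sys, fid$t_end)
    if (is.finite(fid$t_notch)) {
      expect_lt(fid$t_sys, fid$t_notch)
      expect_lt(fid$t_notch, fid$t_end)
    }
  }
})

test_that("shifting a beat shifts every fiducial time by exactly k/fs", {
  b <- generate_beat(beat_morphology(), fs = 120)
  fid0 <- beat_fiducials(make_beat(b$samples, onset_index = 0L))
  k <- 37L
  fid1 <- beat_fiducials(make_beat(b$samples, onset_index = k))
  expect_equal(fid1$t_onset - fid0$t_onset, k / 120)
  expect_equal(fid1$t_sys - fid0$t_sys, k / 120)
  expect_equal(fid1$t_notch - fid0$t_notch, k / 120)
  expect_equal(fid1$apg_a$t - fid0$apg_a$t, k / 120)
  expect_equal(fid1$apg_e$t - fid0$apg_e$t, k / 120)
})
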