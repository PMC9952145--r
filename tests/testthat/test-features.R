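# construct a fiducial set directly for substitution tests
fid_fixture <- function(t_onset = 0, t_sys = 0.2, t_notch = 0.45, t_end = 1.0,
                        amp_sys = 1, amp_notch = 0.4, onset_amp = 0) {
  structure(list(t_onset = t_onset, t_sys = t_sys, amp_sys = amp_sys,
                 t_notch = t_notch, amp_notch = amp_notch, t_end = t_end,
                 apg_a = list(t = 0.1, amp = 50),
                 apg_b = list(t = 0.15, amp = -90),
                 apg_e = list(t = t_notch, amp = 20),
                 notch_source = "derivative-minimum", onset_amp = onset_amp),
            class = "fiducial_set")
}

test_that("timing features follow their fiducial definitions", {
  fid <- fid_fixture()
  nxt <- fid_fixture(t_onset = 1.0, t_sys = 1.2, t_notch = 1.45, t_end = 2.0)
  tf <- timing_features(fid, nxt)
  expect_equal(tf$CT, 0.2)
  expect_equal(tf$PTT, 0.25)
  expect_equal(tf$systolic_time, 0.45)
  expect_equal(tf$diastolic_time, 0.55)
  expect_equal(tf$pulse_interval, 1.0)
  expect_equal(tf$dT, 1.0)
  # telescoping identities
  expect_equal(tf$systolic_time, tf$CT + tf$PTT)
  expect_equal(tf$pulse_interval, tf$systolic_time + tf$diastolic_time)
})

test_that("notch-dependent timings are missing without a notch", {
  fid <- fid_fixture(t_notch = NA_real_, amp_notch = NA_real_)
  tf <- timing_features(fid, NULL)
  expect_true(is.na(tf$PTT) && is.na(tf$systolic_time) &&
                is.na(tf$diastolic_time))
  expect_true(is.na(tf$dT))
  expect_equal(tf$CT, 0.2)
})

test_that("pulse width matches the analytic Gaussian FWHM", {
  fs <- 120
  sigma <- 0.08
  m <- gaussian_morph(center = 0.4, width = sigma, period = 1.0)
  b <- generate_beat(m, fs = fs)
  beat <- make_beat(b$samples, fs = fs)
  fid <- beat_fiducials(beat)
  aw <- amplitude_and_width(beat, fid, baseline = 0)
  expect_lte(abs(aw$PW - 2 * sigma * sqrt(2 * log(2))), 2 / fs)
  expect_equal(aw$SA, max(b$samples), tolerance = 1e-9)
})

test_that("pulse width is invariant under amplitude scaling", {
  fs <- 120
  b <- generate_beat(beat_morphology(), fs = fs)
  beat1 <- make_beat(b$samples, fs = fs)
  beat5 <- make_beat(5 * b$samples, fs = fs)
  aw1 <- amplitude_and_width(beat1, beat_fiducials(beat1))
  aw5 <- amplitude_and_width(beat5, beat_fiducials(beat5))
  expect_equal(aw1$PW, aw5$PW, tolerance = 1e-9)
  expect_equal(aw5$SA, 5 * aw1$SA, tolerance = 1e-6)
})

test_that("areas are exact on a rectangular step fixture", {
  fs <- 100
  # height 1 on [0, 1) s, notch placed at 0.4 s, zero baseline
  beat <- make_beat(rep(1, 100), fs = fs)
  fid <- fid_fixture(t_sys = 0.2, t_notch = 0.4, t_end = 1.0)
  ar <- areas(beat, fid, baseline = 0)
  # trapezoid over k samples spanning (k-1)/fs seconds
  expect_equal(ar$systolic_area, 0.40)
  expect_equal(ar$diastolic_area, 0.59)
  expect_equal(ar$total_area, ar$systolic_area + ar$diastolic_area)
  expect_equal(ar$IPA, 0.59 / 0.40)
})

test_that("area additivity holds on real beats", {
  b <- generate_beat(beat_morphology(), fs = 120)
  beat <- make_beat(b$samples)
  fid <- beat_fiducials(beat)
  ar <- areas(beat, fid)
  expect_equal(ar$total_area, ar$systolic_area + ar$diastolic_area,
               tolerance = 1e-12)
  expect_gt(ar$IPA, 0)
})

test_that("Table-style indices evaluate exactly", {
  feats <- list(SA = 2.0, notch_amp = 1.0, PTT = 0.25, pulse_interval = 1.0,
                CT = 0.2, systolic_time = 0.45, dT = 1.0)
  idx <- indices(feats, height_m = 1.70)
  expect_equal(idx$AI_amp, 0.5)
  expect_equal(idx$RI, 0.5)
  expect_equal(idx$AI_amp + idx$RI, 1.0)
  expect_equal(idx$AI_time, 0.25)
  expect_equal(idx$SI, 1.70 / 0.25)  # 6.8 m/s
  expect_equal(idx$T1, 0.2)
  expect_equal(idx$T2, 0.45)
  expect_equal(idx$T3, 0.25)
  expect_equal(idx$T2, idx$T1 + idx$T3)
})

test_that("missing dT or notch drops exactly the dependent indices", {
  feats <- list(SA = 2.0, notch_amp = 1.0, PTT = 0.25, pulse_interval = 1.0,
                CT = 0.2, systolic_time = 0.45, dT = NA_real_)
  idx <- indices(feats, 1.70)
  expect_true(all(is.na(c(idx$T1, idx$T2, idx$T3))))
  expect_equal(idx$RI, 0.5)
  feats2 <- list(SA = 2.0, notch_amp = NA_real_, PTT = NA_real_,
                 pulse_interval = 1.0, CT = 0.2, systolic_time = NA_real_,
                 dT = 1.0)
  idx2 <- indices(feats2, 1.70)
  expect_true(all(is.na(c(idx2$AI_amp, idx2$RI, idx2$AI_time, idx2$SI,
                          idx2$T2, idx2$T3))))
  expect_equal(idx2$T1, 0.2)
})

test_that("APG ratios are computed on signed amplitudes", {
  waves <- list(a = list(t = 0.1, amp = 2), b = list(t = 0.2, amp = -1),
                e = list(t = 0.4, amp = 0.5))
  af <- apg_features(waves)
  expect_equal(af$b_over_a, -0.5)
  expect_equal(af$e_over_a, 0.25)
  expect_equal(af$b_minus_e_over_a, -0.75)
  waves$e <- NULL
  af2 <- apg_features(waves)
  expect_true(is.na(af2$e) && is.na(af2$e_over_a) &&
                is.na(af2$b_minus_e_over_a))
  expect_equal(af2$b_over_a, -0.5)
})

test_that("the feature catalogue has exactly 24 entries", {
  expect_length(ppg_feature_names(), 24)
  expect_false(anyDuplicated(ppg_feature_names()) > 0)
})

test_that("subject aggregation uses sample statistics feature-wise", {
  bf <- data.frame(subject_id = "S1", beat_index = 1:6, onset_index = 0:5,
                   notch_present = TRUE)
  for (f in ppg_feature_names()) bf[[f]] <- 1.0
  bf$SA <- c(1, 3, 1, 3, 1, 3)
  bf$IPA <- c(2, 2, 2, NA, NA, NA)   # feature-wise missing exclusion
  profile <- data.frame(subject_id = "S1", label = "Healthy", age = 30,
                        height = 1.7, weight = 70, BMI = 24.2, gender = 0,
                        smoking = 0, respiratory_problem = 0,
                        blood_pressure = 0, physical_activity = 1,
                        others = 0, SpO2 = 98, pulse_rate = 70)
  agg <- aggregate_subject(bf, profile)
  expect_equal(agg$SA_mean, 2)
  expect_equal(agg$SA_var, var(c(1, 3, 1, 3, 1, 3)))
  expect_equal(agg$IPA_mean, 2)
  expect_equal(agg$IPA_var, 0)
  expect_equal(agg$CT_var, 0)        # identical beats: zero dispersion
  expect_equal(agg$n_beats_used, 6)
  # permuting beats leaves aggregates unchanged
  agg2 <- aggregate_subject(bf[sample(6), ], profile)
  expect_equal(agg2$SA_mean, agg$SA_mean)
  expect_equal(agg2$SA_var, agg$SA_var)
})

test_that("subjects with too few valid beats are excluded", {
  bf <- data.frame(subject_id = "S1", beat_index = 1:4, onset_index = 0:3,
                   notch_present = TRUE)
  for (f in ppg_feature_names()) bf[[f]] <- 1.0
  profile <- data.frame(subject_id = "S1", label = "Healthy", age = 30,
                        height = 1.7, weight = 70, BMI = 24.2, gender = 0,
                        smoking = 0, respiratory_problem = 0,
                        blood_pressure = 0, physical_activity = 1,
                        others = 0, SpO2 = 98, pulse_rate = 70)
  expect_error(aggregate_subject(bf, profile),
               class = "ppg_subject_excluded")
})

test_that("feature recovery matches ground truth on noise-free recordings", {
  m <- beat_morphology()
  rec <- generate_recording(m, fs = 120, duration = 20, subject_id = "S1")
  bf <- extract_beat_features(rec$record, height_m = 1.70)
  tr <- rec$truth
  # match by onset; compare timing features to analytic truth
  ct_err <- ptt_err <- sa_rel <- rep(NA_real_, nrow(bf))
  for (i in seq_len(nrow(bf))) {
    j <- which.min(abs(tr$t_onset - bf$onset_index[i] / 120))
    ct_err[i] <- bf$CT[i] - (tr$t_sys[j] - tr$t_onset[j])
    ptt_err[i] <- bf$PTT[i] - (tr$t_notch[j] - tr$t_sys[j])
    sa_rel[i] <- abs(bf$SA[i] - tr$amp_sys[j]) / tr$amp_sys[j]
  }
  # peak-to-notch timing is convention-free: within 2 samples of truth
  expect_lte(max(abs(ptt_err), na.rm = TRUE), 2 / 120)
  # interior beats only below: the first and last sit on filter transients
  interior <- 2:(nrow(bf) - 1)
  # crest time differs from the boundary-convention truth only by the
  # onset convention: a constant offset of a few samples, tight spread
  expect_lte(max(abs(ct_err[interior])), 8 / 120)
  expect_lte(diff(range(ct_err[interior])), 2 / 120)
  # amplitude within a few percent (filter distortion included)
  expect_lt(max(sa_rel[interior]), 0.05)
  expect_true(all(bf$SI > 0 & is.finite(bf$SI), na.rm = TRUE))
})
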