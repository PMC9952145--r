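test_that("generated beat matches dense-grid numerical landmarks", {
  m <- beat_morphology(systolic_amp = 1.0, diastolic_amp = 0.5,
                       beat_period = 1.0)
  b <- generate_beat(m, fs = 120)
  # independent oracle: dense-grid maximization of the analytic waveform
  tt <- seq(0, m$beat_period, length.out = 2e5)
  yy <- ppgscreen:::eval_beat(m, tt)
  t_max <- tt[which.max(yy)]
  expect_lt(abs(b$truth$t_sys - t_max), 1 / 120)
  # notch oracle: dense-grid minimization between the two component peaks
  between <- tt > t_max & tt < m$diastolic_center
  t_min <- tt[between][which.min(yy[between])]
  expect_true(b$truth$has_notch)
  expect_lt(abs(b$truth$t_notch - t_min), 1 / 120)
})

test_that("systolic-only beats carry no notch in the ground truth", {
  b <- generate_beat(gaussian_morph(), fs = 120)
  expect_false(b$truth$has_notch)
  expect_false(b$truth$has_diastolic)
  expect_true(is.na(b$truth$t_notch))
})

test_that("doubling the systolic amplitude doubles the systolic component", {
  m1 <- gaussian_morph(amp = 1)
  m2 <- gaussian_morph(amp = 2)
  b1 <- generate_beat(m1, fs = 120)
  b2 <- generate_beat(m2, fs = 120)
  expect_equal(b2$samples, 2 * b1$samples, tolerance = 1e-12)
})

test_that("coarse sampling relative to component width is rejected", {
  m <- gaussian_morph(width = 0.05)
  expect_error(generate_beat(m, fs = 40), class = "ppg_resolution_error")
})

test_that("degenerate disturbances give an exact tiling of one beat", {
  m <- beat_morphology(beat_period = 1.0)
  b <- generate_beat(m, fs = 120)
  rec <- generate_recording(m, fs = 120, duration = 10)
  expect_equal(length(rec$record$samples), 10 * length(b$samples))
  expect_equal(rec$record$samples, rep(b$samples, 10), tolerance = 1e-12)
  expect_equal(nrow(rec$truth), 10)  # floor(duration / period)
  expect_true(all(diff(rec$truth$t_onset) == 1.0))
})

test_that("recordings are reproducible for a fixed seed", {
  m <- beat_morphology()
  gen <- function() {
    set.seed(99)
    generate_recording(m, fs = 120, duration = 20, beat_jitter_sd = 0.02,
                       amplitude_jitter_frac = 0.05, noise_sd = 0.01)
  }
  r1 <- gen(); r2 <- gen()
  expect_identical(r1$record$samples, r2$record$samples)
  expect_identical(r1$truth, r2$truth)
})

test_that("default cohort reproduces the study composition", {
  cfg <- generator_config()
  expect_equal(unname(cfg$n_per_class["Healthy"]), 200)
  expect_equal(unname(cfg$n_per_class["ACS"]), 63)
  expect_equal(unname(cfg$n_per_class[c("CVA", "DVT", "HF", "AF")]),
               c(50, 23, 13, 13))
})

test_that("cohort generation honours per-class counts and determinism", {
  cfg <- noise_free_config(n_per_class = c(Healthy = 2, ACS = 2, CVA = 2,
                                           DVT = 2, HF = 2, AF = 2),
                           duration = 10, seed = 5)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$subjects), 12)
  expect_equal(unname(table(coh$subjects$label)["ACS"]), 2)
  coh2 <- generate_cohort(cfg)
  expect_identical(coh$subjects, coh2$subjects)
  expect_identical(coh$recordings[["AF_001"]]$samples,
                   coh2$recordings[["AF_001"]]$samples)
  # ground-truth beat times strictly increase within each subject
  for (tr in coh$truth) expect_true(all(diff(tr$t_onset) > 0))
})

test_that("empty class configuration is rejected", {
  expect_error(generator_config(n_per_class = integer(0)),
               class = "ppg_config_error")
})

test_that("true notch amplitude separates healthy from CVD classes", {
  cfg <- noise_free_config(n_per_class = c(Healthy = 50, ACS = 17, CVA = 17,
                                           DVT = 16),
                           duration = 3, seed = 21)
  coh <- generate_cohort(cfg)
  subj_notch <- vapply(coh$subjects$subject_id, function(sid) {
    tr <- coh$truth[[sid]]
    mean(tr$amp_notch, na.rm = TRUE)
  }, numeric(1))
  healthy <- coh$subjects$label == "Healthy"
  tt <- t.test(subj_notch[healthy], subj_notch[!healthy])
  expect_lt(tt$p.value, 0.05)
})

test_that("cohorts round-trip to plain-text files", {
  cfg <- noise_free_config(n_per_class = c(Healthy = 1, HF = 1),
                           duration = 5, seed = 3)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "subjects.csv")))
  sig <- read.csv(file.path(dir, "signals", "Healthy_001.csv"))
  expect_equal(names(sig), c("time_s", "amplitude"))
  expect_equal(sig$amplitude, coh$recordings[["Healthy_001"]]$samples,
               tolerance = 1e-6)
  truth <- read.csv(file.path(dir, "ground_truth.csv"))
  expect_setequal(unique(truth$subject_id), c("Healthy_001", "HF_001"))
})
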