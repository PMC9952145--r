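#' Beat morphology: a two-component pulse model
#'
#' A single PPG pulse is modelled as the sum of two Gaussian-shaped
#' components: a systolic ejection wave and a (possibly absent) diastolic
#' reflection wave. This is the simplest waveform exhibiting every landmark
#' the feature set needs — onset, systolic peak, dicrotic notch (the local
#' minimum between the two components), diastolic peak and end — while
#' keeping all of them analytically recoverable, which is what makes the
#' generator usable as a ground-truth benchmark.
#'
#' @param systolic_amp systolic component amplitude (a.u., > 0).
#' @param systolic_center systolic component centre (s).
#' @param systolic_width systolic component Gaussian sd (s).
#' @param diastolic_amp diastolic component amplitude (a.u., >= 0); 0 gives
#'   a systolic-only pulse with no dicrotic notch, the waveform shape
#'   reported in stiff-artery and CVD subjects.
#' @param diastolic_center diastolic component centre (s).
#' @param diastolic_width diastolic component Gaussian sd (s).
#' @param beat_period beat length (s).
#' @return an object of class `beat_morphology`.
#' @export
beat_morphology <- function(systolic_amp = 1.0,
                            systolic_center = 0.25,
                            systolic_width = 0.07,
                            diastolic_amp = 0.45,
                            diastolic_center = 0.55,
                            diastolic_width = 0.11,
                            beat_period = 0.85) {
  stopifnot(systolic_amp > 0, diastolic_amp >= 0,
            systolic_width > 0, diastolic_width > 0, beat_period > 0)
  if (!(systolic_center < diastolic_center && diastolic_center < beat_period))
    abort_ppg("ppg_config_error",
              "need systolic_center < diastolic_center < beat_period")
  if (diastolic_amp > systolic_amp)
    abort_ppg("ppg_config_error", "diastolic_amp must not exceed systolic_amp")
  structure(list(systolic_amp = systolic_amp,
                 systolic_center = systolic_center,
                 systolic_width = systolic_width,
                 diastolic_amp = diastolic_amp,
                 diastolic_center = diastolic_center,
                 diastolic_width = diastolic_width,
                 beat_period = beat_period),
            class = "beat_morphology")
}

## Evaluate the two-component pulse at times t (vectorised).
eval_beat <- function(morph, t) {
  y <- morph$systolic_amp *
    exp(-(t - morph$systolic_center)^2 / (2 * morph$systolic_width^2))
  if (morph$diastolic_amp > 0) {
    y <- y + morph$diastolic_amp *
      exp(-(t - morph$diastolic_center)^2 / (2 * morph$diastolic_width^2))
  }
  y
}

## Dense-grid + parabolic-refined landmark search on the analytic pulse.
## Returns the true systolic peak, the inter-component minimum (notch, NA if
## absent), and the diastolic peak. A notch whose depth below the diastolic
## peak is under `min_notch_depth_frac` of the systolic amplitude is marked
## absent: such a dip is far below sampling/measurement resolution, and the
## pulse is a shoulder-type wave for any detector.
beat_landmarks <- function(morph, n_grid = 4096, min_notch_depth_frac = 0.01) {
  tt <- seq(0, morph$beat_period, length.out = n_grid)
  yy <- eval_beat(morph, tt)
  ## systolic peak: global maximum (first and highest)
  i_sys <- which.max(yy)
  sys <- refine_extremum(tt, yy, i_sys)
  notch <- list(t = NA_real_, y = NA_real_)
  dia <- list(t = NA_real_, y = NA_real_)
  if (morph$diastolic_amp > 0) {
    ## diastolic peak: maximum after the systolic peak region
    right <- which(tt > sys$t + 2 * morph$systolic_width * 0.5)
    if (length(right) > 2) {
      seg <- yy[right]
      pk <- find_peaks(seg, min_prominence = 1e-12)
      if (length(pk)) {
        i_d <- right[pk[which.max(seg[pk])]]
        dia <- refine_extremum(tt, yy, i_d)
        ## notch: minimum strictly between the two peaks
        between <- which(tt > sys$t & tt < dia$t)
        if (length(between) > 2) {
          i_n <- between[which.min(yy[between])]
          if (i_n > min(between) && i_n < max(between)) {
            cand <- refine_extremum(tt, yy, i_n)
            depth <- dia$y - cand$y
            if (depth >= min_notch_depth_frac * morph$systolic_amp)
              notch <- cand
          }
        }
      }
    }
  }
  list(t_sys = sys$t, amp_sys = sys$y,
       t_notch = notch$t, amp_notch = notch$y,
       t_dia = dia$t, amp_dia = dia$y)
}

#' Generate one sampled beat with analytic ground truth
#'
#' @param morph a [beat_morphology()].
#' @param fs sampling rate (Hz). Each Gaussian width must cover at least
#'   4 samples or the beat is deemed unresolvable.
#' @return list with `samples` (length `round(beat_period * fs)`), `fs`,
#'   and `truth`: a one-row data frame of ground-truth landmark times (s,
#'   beat-local) and amplitudes, with `has_notch` flag.
#' @export
generate_beat <- function(morph, fs) {
  stopifnot(inherits(morph, "beat_morphology"), fs > 0)
  if (fs * morph$systolic_width < 4 ||
      (morph$diastolic_amp > 0 && fs * morph$diastolic_width < 4))
    abort_ppg("ppg_resolution_error",
              "sampling rate too coarse: fewer than 4 samples per component width")
  n <- round(morph$beat_period * fs)
  t <- (seq_len(n) - 1L) / fs
  y <- eval_beat(morph, t)
  lm <- beat_landmarks(morph)
  truth <- data.frame(
    t_onset = 0, t_sys = lm$t_sys, amp_sys = lm$amp_sys,
    t_notch = lm$t_notch, amp_notch = lm$amp_notch,
    t_dia = lm$t_dia, amp_dia = lm$amp_dia,
    t_end = n / fs, has_notch = is.finite(lm$t_notch),
    has_diastolic = morph$diastolic_amp > 0
  )
  list(samples = y, fs = fs, truth = truth)
}

#' Cohort generator configuration
#'
#' Defaults reproduce the study composition this package emulates: a
#' 362-subject cohort of 200 healthy subjects and five cardiovascular
#' disease (CVD) classes — acute coronary syndrome (ACS, 63), cerebrovascular
#' accident (CVA, 50), deep vein thrombosis (DVT, 23), heart failure (HF, 13)
#' and atrial fibrillation (AF, 13) — recorded for 120 s at 120 Hz. Disease
#' classes carry the morphological signatures reported for CVD pulses:
#' attenuated (sometimes absent) diastolic wave, longer crest time, and
#' class-specific heart rates; demographic priors make CVD subjects older,
#' more hypertensive and more frequent smokers.
#'
#' @param n_per_class named integer vector of subjects per class.
#' @param fs sampling rate (Hz).
#' @param duration recording length (s); at least two minutes by default.
#' @param class_morphology named list (per class) of lists with elements
#'   `mean` (a [beat_morphology()]) and `sd` (named numeric vector of
#'   between-subject sds for any morphology parameter).
#' @param beat_jitter_sd within-subject sd of the beat period (s).
#' @param amplitude_jitter_frac within-subject fractional amplitude jitter.
#' @param baseline_wander_amp amplitude of the respiratory baseline drift (a.u.).
#' @param baseline_wander_freq respiratory drift frequency (Hz); the default
#'   0.25 Hz sits inside the band the preprocessing filter removes.
#' @param noise_sd white measurement noise sd (a.u.).
#' @param demographics_priors named list (per class) of demographic prior
#'   parameters; see [default_demographics_priors()].
#' @param seed integer seed; every stochastic draw in the generator flows
#'   from it.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_per_class = c(Healthy = 200, ACS = 63, CVA = 50,
                                             DVT = 23, HF = 13, AF = 13),
                             fs = 120,
                             duration = 120,
                             class_morphology = default_class_morphology(),
                             beat_jitter_sd = 0.02,
                             amplitude_jitter_frac = 0.05,
                             baseline_wander_amp = 0.2,
                             baseline_wander_freq = 0.25,
                             noise_sd = 0.01,
                             demographics_priors = default_demographics_priors(),
                             seed = 1L) {
  if (!length(n_per_class)) abort_ppg("ppg_config_error", "empty class list")
  if (any(n_per_class < 1)) abort_ppg("ppg_config_error", "class counts must be >= 1")
  if (is.null(names(n_per_class)) || any(!nzchar(names(n_per_class))))
    abort_ppg("ppg_config_error", "n_per_class must be named by class label")
  missing_m <- setdiff(names(n_per_class), names(class_morphology))
  if (length(missing_m))
    abort_ppg("ppg_config_error",
              paste("no morphology prior for class:", paste(missing_m, collapse = ", ")))
  structure(list(n_per_class = n_per_class, fs = fs, duration = duration,
                 class_morphology = class_morphology,
                 beat_jitter_sd = beat_jitter_sd,
                 amplitude_jitter_frac = amplitude_jitter_frac,
                 baseline_wander_amp = baseline_wander_amp,
                 baseline_wander_freq = baseline_wander_freq,
                 noise_sd = noise_sd,
                 demographics_priors = demographics_priors,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Default per-class beat morphology priors
#'
#' Healthy pulses have a tall diastolic wave and a clear dicrotic notch;
#' disease classes attenuate the diastolic wave (heart failure most, down to
#' a shoulder), lengthen the crest time, and shift the heart rate (AF fast
#' and irregular, HF slow). Between-subject variation is Gaussian on each
#' parameter with the listed sds.
#'
#' @return named list of per-class priors (`mean` morphology + `sd` vector).
#' @export
default_class_morphology <- function() {
  sd_common <- c(systolic_amp = 0.08, systolic_center = 0.015,
                 systolic_width = 0.005, diastolic_amp = 0.05,
                 diastolic_center = 0.02, diastolic_width = 0.008,
                 beat_period = 0.03)
  prior <- function(...) list(mean = beat_morphology(...), sd = sd_common)
  list(
    Healthy = prior(systolic_amp = 1.00, systolic_center = 0.25,
                    systolic_width = 0.070, diastolic_amp = 0.45,
                    diastolic_center = 0.55, diastolic_width = 0.110,
                    beat_period = 0.85),
    ACS     = prior(systolic_amp = 0.90, systolic_center = 0.30,
                    systolic_width = 0.085, diastolic_amp = 0.22,
                    diastolic_center = 0.58, diastolic_width = 0.110,
                    beat_period = 0.80),
    CVA     = prior(systolic_amp = 0.95, systolic_center = 0.32,
                    systolic_width = 0.080, diastolic_amp = 0.28,
                    diastolic_center = 0.60, diastolic_width = 0.105,
                    beat_period = 0.90),
    DVT     = prior(systolic_amp = 0.92, systolic_center = 0.28,
                    systolic_width = 0.075, diastolic_amp = 0.32,
                    diastolic_center = 0.56, diastolic_width = 0.100,
                    beat_period = 0.78),
    HF      = prior(systolic_amp = 0.75, systolic_center = 0.34,
                    systolic_width = 0.100, diastolic_amp = 0.12,
                    diastolic_center = 0.62, diastolic_width = 0.110,
                    beat_period = 1.00),
    AF      = prior(systolic_amp = 0.88, systolic_center = 0.27,
                    systolic_width = 0.072, diastolic_amp = 0.20,
                    diastolic_center = 0.54, diastolic_width = 0.100,
                    beat_period = 0.70)
  )
}

#' Default per-class demographic priors
#'
#' Ten background variables plus oximeter readings. Continuous variables are
#' Gaussian (age in years, height in m, BMI in kg/m2, SpO2 in %), flags are
#' Bernoulli. Weight is derived as BMI x height^2 so the BMI identity holds
#' exactly. CVD classes are older, heavier, more hypertensive, smoke more
#' and exercise less; heart failure lowers SpO2.
#'
#' @return named list of per-class prior parameter lists.
#' @export
default_demographics_priors <- function() {
  base <- function(age_mean, age_sd, bmi_mean, spo2_mean, spo2_sd,
                   p_smoking, p_resp, p_bp, p_activity, p_others) {
    list(age_mean = age_mean, age_sd = age_sd,
         height_mean = 1.70, height_sd = 0.09,
         bmi_mean = bmi_mean, bmi_sd = 2.5,
         spo2_mean = spo2_mean, spo2_sd = spo2_sd,
         p_female = 0.5, p_smoking = p_smoking, p_resp = p_resp,
         p_bp = p_bp, p_activity = p_activity, p_others = p_others)
  }
  list(
    Healthy = base(35, 12, 24, 98.0, 0.8, 0.20, 0.05, 0.15, 0.60, 0.05),
    ACS     = base(62,  9, 28, 96.0, 1.0, 0.55, 0.20, 0.60, 0.20, 0.20),
    CVA     = base(68,  8, 27, 96.5, 1.0, 0.45, 0.15, 0.70, 0.15, 0.25),
    DVT     = base(55, 10, 29, 97.0, 1.0, 0.40, 0.10, 0.45, 0.25, 0.30),
    HF      = base(70,  8, 26, 92.0, 2.0, 0.40, 0.50, 0.65, 0.10, 0.35),
    AF      = base(72,  9, 26, 95.0, 1.5, 0.35, 0.25, 0.70, 0.10, 0.25)
  )
}

## Draw one subject's morphology from a class prior; parameters are clamped
## to keep the beat model valid (ordering, positivity).
draw_morphology <- function(prior) {
  m <- prior$mean
  s <- prior$sd
  draw <- function(name, lo = -Inf, hi = Inf) {
    v <- m[[name]] + stats::rnorm(1, 0, s[[name]])
    min(max(v, lo), hi)
  }
  sys_amp <- draw("systolic_amp", lo = 0.2)
  sys_c   <- draw("systolic_center", lo = 0.12)
  sys_w   <- draw("systolic_width", lo = 0.04)
  dia_amp <- if (m$diastolic_amp > 0) draw("diastolic_amp", lo = 0) else 0
  dia_amp <- min(dia_amp, sys_amp)
  dia_c   <- draw("diastolic_center", lo = sys_c + 0.12)
  dia_w   <- draw("diastolic_width", lo = 0.05)
  period  <- draw("beat_period", lo = dia_c + 0.15)
  beat_morphology(systolic_amp = sys_amp, systolic_center = sys_c,
                  systolic_width = sys_w, diastolic_amp = dia_amp,
                  diastolic_center = dia_c, diastolic_width = dia_w,
                  beat_period = period)
}

draw_demographics <- function(prior) {
  age <- max(18, stats::rnorm(1, prior$age_mean, prior$age_sd))
  height <- max(1.4, stats::rnorm(1, prior$height_mean, prior$height_sd))
  bmi <- max(16, stats::rnorm(1, prior$bmi_mean, prior$bmi_sd))
  weight <- bmi * height^2
  spo2 <- min(100, max(70, stats::rnorm(1, prior$spo2_mean, prior$spo2_sd)))
  list(age = age, height = height, weight = weight, BMI = bmi,
       gender = stats::rbinom(1, 1, prior$p_female),
       smoking = stats::rbinom(1, 1, prior$p_smoking),
       respiratory_problem = stats::rbinom(1, 1, prior$p_resp),
       blood_pressure = stats::rbinom(1, 1, prior$p_bp),
       physical_activity = stats::rbinom(1, 1, prior$p_activity),
       others = stats::rbinom(1, 1, prior$p_others),
       SpO2 = spo2)
}

#' Generate one subject's recording with ground truth
#'
#' Beats drawn from the subject morphology are concatenated with
#' period jitter and per-beat amplitude jitter, then a sinusoidal
#' respiratory baseline drift and white measurement noise are added.
#' Setting all three disturbance amplitudes to zero yields an exact tiling
#' of the subject's canonical beat.
#'
#' @param morph subject-level [beat_morphology()].
#' @param fs sampling rate (Hz).
#' @param duration target length (s); beats are appended while they fit, so
#'   the recording spans an integer number of beats.
#' @param beat_jitter_sd,amplitude_jitter_frac,baseline_wander_amp,baseline_wander_freq,noise_sd
#'   disturbance parameters; see [generator_config()].
#' @param subject_id identifier stored on the record.
#' @return list with `record` (class `ppg_record`: `subject_id`, `fs`,
#'   `samples`, `t0`) and `truth` (data frame, one row per generated beat;
#'   times are absolute seconds in the recording).
#' @export
generate_recording <- function(morph, fs, duration,
                               beat_jitter_sd = 0,
                               amplitude_jitter_frac = 0,
                               baseline_wander_amp = 0,
                               baseline_wander_freq = 0.25,
                               noise_sd = 0,
                               subject_id = "S1") {
  stopifnot(inherits(morph, "beat_morphology"))
  if (duration < morph$beat_period)
    abort_ppg("ppg_config_error", "duration shorter than one beat period")
  if (fs * morph$systolic_width < 4 ||
      (morph$diastolic_amp > 0 && fs * morph$diastolic_width < 4))
    abort_ppg("ppg_resolution_error",
              "sampling rate too coarse: fewer than 4 samples per component width")
  ## landmark times are invariant under uniform amplitude scaling and under
  ## period changes (the components stay put; only the beat end moves), so
  ## one dense-grid search serves every jittered copy of the beat
  lm <- beat_landmarks(morph)
  chunks <- list()
  t0s <- n_is <- scales <- numeric(0)
  cursor_samples <- 0L
  k <- 0L
  repeat {
    period <- morph$beat_period
    if (beat_jitter_sd > 0) {
      period <- period + stats::rnorm(1, 0, beat_jitter_sd)
      period <- min(max(period, morph$diastolic_center + 0.12),
                    1.8 * morph$beat_period)
    }
    if (cursor_samples / fs + period > duration + 1e-9) break
    scale <- 1
    if (amplitude_jitter_frac > 0)
      scale <- max(0.3, 1 + stats::rnorm(1, 0, amplitude_jitter_frac))
    n_i <- round(period * fs)
    t_i <- (seq_len(n_i) - 1L) / fs
    k <- k + 1L
    t0s[k] <- cursor_samples / fs
    n_is[k] <- n_i
    scales[k] <- scale
    chunks[[k]] <- scale * eval_beat(morph, t_i)
    cursor_samples <- cursor_samples + n_i
  }
  samples <- unlist(chunks, use.names = FALSE)
  truth <- if (k) list(data.frame(
    t_onset = t0s, t_sys = t0s + lm$t_sys, amp_sys = scales * lm$amp_sys,
    t_notch = t0s + lm$t_notch, amp_notch = scales * lm$amp_notch,
    t_dia = t0s + lm$t_dia, amp_dia = scales * lm$amp_dia,
    t_end = t0s + n_is / fs, has_notch = is.finite(lm$t_notch),
    has_diastolic = morph$diastolic_amp > 0,
    beat_index = seq_len(k)
  )) else list()
  if (!k) abort_ppg("ppg_config_error", "no beats fit in the requested duration")
  n <- length(samples)
  t <- (seq_len(n) - 1L) / fs
  if (baseline_wander_amp > 0)
    samples <- samples + baseline_wander_amp * sin(2 * pi * baseline_wander_freq * t)
  if (noise_sd > 0)
    samples <- samples + stats::rnorm(n, 0, noise_sd)
  truth <- do.call(rbind, truth)
  truth$subject_id <- subject_id
  record <- structure(list(subject_id = subject_id, fs = fs,
                           samples = samples, t0 = 0),
                      class = "ppg_record")
  list(record = record, truth = truth)
}

#' Generate a full synthetic cohort
#'
#' Draws per-subject morphologies and demographics from the per-class
#' priors, simulates one recording per subject, and returns the cohort with
#' its per-beat ground truth. Reproducible: the same configuration and seed
#' give an identical cohort.
#'
#' @param config a [generator_config()].
#' @param seed optional integer overriding `config$seed`.
#' @return list of class `ppg_cohort` with elements `subjects` (data frame:
#'   subject_id, label, demographics, SpO2, pulse_rate), `recordings`
#'   (named list of `ppg_record`), `truth` (named list of per-beat truth
#'   data frames), and `config`.
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  classes <- names(config$n_per_class)
  subjects <- list()
  recordings <- list()
  truths <- list()
  idx <- 0L
  for (cls in classes) {
    prior_m <- config$class_morphology[[cls]]
    prior_d <- config$demographics_priors[[cls]]
    for (j in seq_len(config$n_per_class[[cls]])) {
      idx <- idx + 1L
      sid <- sprintf("%s_%03d", cls, j)
      morph <- draw_morphology(prior_m)
      demo <- draw_demographics(prior_d)
      rec <- generate_recording(
        morph, fs = config$fs, duration = config$duration,
        beat_jitter_sd = config$beat_jitter_sd,
        amplitude_jitter_frac = config$amplitude_jitter_frac,
        baseline_wander_amp = config$baseline_wander_amp,
        baseline_wander_freq = config$baseline_wander_freq,
        noise_sd = config$noise_sd,
        subject_id = sid
      )
      ## device-style pulse rate: rate implied by the subject's mean period,
      ## with a small reading error
      pulse_rate <- 60 / mean(diff(rec$truth$t_sys)) + stats::rnorm(1, 0, 1)
      subjects[[idx]] <- data.frame(
        subject_id = sid, label = cls,
        age = demo$age, height = demo$height, weight = demo$weight,
        BMI = demo$BMI, gender = demo$gender, smoking = demo$smoking,
        respiratory_problem = demo$respiratory_problem,
        blood_pressure = demo$blood_pressure,
        physical_activity = demo$physical_activity, others = demo$others,
        SpO2 = demo$SpO2, pulse_rate = pulse_rate,
        stringsAsFactors = FALSE
      )
      recordings[[sid]] <- rec$record
      truths[[sid]] <- rec$truth
    }
  }
  structure(list(subjects = do.call(rbind, subjects),
                 recordings = recordings, truth = truths, config = config),
            class = "ppg_cohort")
}

#' Write a cohort to disk as plain-text files
#'
#' One two-column CSV (`time_s`, `amplitude`) plus a JSON sidecar per
#' recording, a cohort-level subject table, and the ground-truth beat table.
#'
#' @param cohort a `ppg_cohort`.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig_dir <- file.path(dir, "signals")
  dir.create(sig_dir, showWarnings = FALSE)
  for (sid in names(cohort$recordings)) {
    rec <- cohort$recordings[[sid]]
    t <- rec$t0 + (seq_along(rec$samples) - 1) / rec$fs
    utils::write.csv(data.frame(time_s = t, amplitude = rec$samples),
                     file.path(sig_dir, paste0(sid, ".csv")), row.names = FALSE)
    label <- cohort$subjects$label[cohort$subjects$subject_id == sid]
    writeLines(sprintf('{"subject_id": "%s", "fs_hz": %g, "label": "%s"}',
                       sid, rec$fs, label),
               file.path(sig_dir, paste0(sid, ".json")))
  }
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, cohort$truth),
                   file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}
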