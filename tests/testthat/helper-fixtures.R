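# Fixtures are built in code: beats wrapped from raw sample vectors, small
# noise-free cohorts, and random morphologies drawn from the class priors.

make_beat <- function(samples, fs = 120, onset_index = 0L, subject_id = "T1",
                      beat_index = 1L) {
  structure(list(subject_id = subject_id, beat_index = beat_index,
                 onset_index = as.integer(onset_index),
                 end_index = as.integer(onset_index + length(samples)),
                 samples = samples, fs = fs),
            class = "ppg_beat")
}

make_record <- function(samples, fs = 120, subject_id = "T1") {
  structure(list(subject_id = subject_id, fs = fs, samples = samples, t0 = 0),
            class = "ppg_record")
}

# single-Gaussian (systolic-only) morphology
gaussian_morph <- function(amp = 1, center = 0.30, width = 0.07, period = 1.0) {
  beat_morphology(systolic_amp = amp, systolic_center = center,
                  systolic_width = width, diastolic_amp = 0,
                  diastolic_center = center + 0.2, diastolic_width = 0.1,
                  beat_period = period)
}

# noise-free cohort configuration (all disturbances off)
noise_free_config <- function(n_per_class, duration = 30, seed = 1L, ...) {
  generator_config(n_per_class = n_per_class, duration = duration,
                   beat_jitter_sd = 0, amplitude_jitter_frac = 0,
                   baseline_wander_amp = 0, noise_sd = 0, seed = seed, ...)
}

# one random morphology per call, drawn from a randomly chosen class prior
random_morphology <- function() {
  priors <- default_class_morphology()
  ppgscreen:::draw_morphology(priors[[sample(length(priors), 1)]])
}

# synthetic tabular dataset: one informative feature (class means separated
# by `effect` sds) + `n_noise` standard-normal noise features
planted_dataset <- function(n = 100, n_noise = 10, effect = 2) {
  y <- factor(rep(c("A", "B"), length.out = n))
  d <- data.frame(subject_id = sprintf("S%03d", seq_len(n)), label = y)
  d$signal <- stats::rnorm(n, mean = ifelse(y == "A", 0, effect), sd = 1)
  for (j in seq_len(n_noise)) d[[paste0("noise", j)]] <- stats::rnorm(n)
  d
}
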