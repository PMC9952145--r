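#' The per-beat time-domain feature catalogue
#'
#' The 24 per-beat features: systolic amplitude (SA), peak-to-peak interval
#' (dT), pulse interval, crest time (CT), pulse width at half height (PW),
#' dicrotic-notch amplitude, systolic time (onset to notch), diastolic time
#' (notch to end), pulse transit time (PTT, peak to notch), total area
#' under the pulse, inflection point area ratio (IPA), augmentation index
#' of amplitude (AI_amp), reflection index (RI), augmentation index of time
#' (AI_time), stiffness index (SI), the three time ratios T1–T3, the APG
#' a, b, e amplitudes and the ratios b/a, e/a, (b−e)/a.
#'
#' @return character vector of the 24 feature names, in declaration order.
#' @export
ppg_feature_names <- function() {
  c("SA", "dT", "pulse_interval", "CT", "PW", "notch_amp",
    "systolic_time", "diastolic_time", "PTT",
    "total_area", "IPA",
    "AI_amp", "RI", "AI_time", "SI", "T1", "T2", "T3",
    "a", "b", "e", "b_over_a", "e_over_a", "b_minus_e_over_a")
}

#' Timing features of one beat
#'
#' Pulse interval = onset to end (two consecutive pulse minima); crest time
#' CT = onset to systolic peak; PTT = systolic peak to dicrotic notch;
#' systolic time = onset to notch (so systolic_time = CT + PTT by
#' construction); diastolic time = notch to end; dT = peak-to-peak interval
#' to the *next* beat's systolic peak (missing for the last beat). Notch
#' absent makes PTT, systolic and diastolic time missing.
#'
#' @param fid a `fiducial_set`.
#' @param next_fid the next consecutive beat's `fiducial_set`, or `NULL`.
#' @return named list: `pulse_interval`, `dT`, `CT`, `systolic_time`,
#'   `diastolic_time`, `PTT` (s; `NA` where undefined).
#' @export
timing_features <- function(fid, next_fid = NULL) {
  stopifnot(inherits(fid, "fiducial_set"))
  if (!(fid$t_onset < fid$t_sys && fid$t_sys < fid$t_end))
    abort_ppg("ppg_malformed_beat", "fiducial ordering violated")
  has_notch <- is.finite(fid$t_notch)
  if (has_notch && !(fid$t_sys < fid$t_notch && fid$t_notch < fid$t_end))
    abort_ppg("ppg_malformed_beat", "notch outside (t_sys, t_end)")
  list(
    pulse_interval = fid$t_end - fid$t_onset,
    dT = if (is.null(next_fid)) NA_real_ else next_fid$t_sys - fid$t_sys,
    CT = fid$t_sys - fid$t_onset,
    systolic_time = if (has_notch) fid$t_notch - fid$t_onset else NA_real_,
    diastolic_time = if (has_notch) fid$t_end - fid$t_notch else NA_real_,
    PTT = if (has_notch) fid$t_notch - fid$t_sys else NA_real_
  )
}

#' Amplitude features and pulse width of one beat
#'
#' Amplitudes are measured above the per-beat baseline (the value at
#' onset): SA is the systolic rise, notch_amp the notch rise. PW is the
#' width of the half-height region containing the systolic peak, with
#' sub-sample linear interpolation at both crossings.
#'
#' @param beat a `ppg_beat`.
#' @param fid its `fiducial_set`.
#' @param baseline baseline amplitude; defaults to the beat's onset value.
#' @return named list `SA`, `notch_amp` (`NA` if no notch), `PW`.
#' @export
amplitude_and_width <- function(beat, fid, baseline = fid$onset_amp) {
  stopifnot(inherits(beat, "ppg_beat"), inherits(fid, "fiducial_set"))
  x <- beat$samples
  fs <- beat$fs
  SA <- fid$amp_sys - baseline
  if (!is.finite(SA) || SA <= 0)
    abort_ppg("ppg_malformed_beat", "non-positive systolic amplitude")
  notch_amp <- if (is.finite(fid$amp_notch)) fid$amp_notch - baseline else NA_real_
  level <- baseline + SA / 2
  i_sys <- round(fid$t_sys * fs) - beat$onset_index + 1L
  above <- x >= level
  if (!above[i_sys]) abort_ppg("ppg_malformed_beat", "peak below its own half height")
  ## contiguous half-height run containing the systolic peak
  lo <- i_sys
  while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- i_sys
  while (hi < length(x) && above[hi + 1L]) hi <- hi + 1L
  if (lo == 1L || hi == length(x))
    abort_ppg("ppg_malformed_beat", "beat never drops below half height")
  ## sub-sample crossings by linear interpolation
  t_lo <- (lo - 1L) - (x[lo] - level) / (x[lo] - x[lo - 1L])
  t_hi <- (hi - 1L) + (level - x[hi]) / (x[hi + 1L] - x[hi])
  list(SA = SA, notch_amp = notch_amp, PW = (t_hi - t_lo) / fs)
}

#' Pulse areas and the inflection point area ratio
#'
#' Trapezoidal integration of the baseline-subtracted beat, split at the
#' dicrotic notch: the systolic area runs onset to notch, the diastolic
#' area notch to end, and their sum is the total area exactly (shared
#' boundary ordinate). IPA = diastolic / systolic area, a proxy for total
#' peripheral resistance.
#'
#' @param beat a `ppg_beat`.
#' @param fid its `fiducial_set` (notch required).
#' @param baseline baseline amplitude; defaults to the onset value.
#' @return named list `total_area`, `systolic_area`, `diastolic_area`
#'   (a.u.·s), `IPA`.
#' @export
areas <- function(beat, fid, baseline = fid$onset_amp) {
  stopifnot(inherits(beat, "ppg_beat"), inherits(fid, "fiducial_set"))
  if (!is.finite(fid$t_notch))
    abort_ppg("ppg_malformed_beat", "areas undefined without a dicrotic notch")
  x <- beat$samples - baseline
  fs <- beat$fs
  k <- round(fid$t_notch * fs) - beat$onset_index + 1L
  n <- length(x)
  if (k < 2L || k > n - 1L)
    abort_ppg("ppg_malformed_beat", "notch too close to the beat boundary")
  trapz <- function(y) if (length(y) < 2) 0 else sum((y[-1] + y[-length(y)]) / 2) / fs
  sys_area <- trapz(x[1:k])
  dia_area <- trapz(x[k:n])
  if (sys_area <= 0)
    abort_ppg("ppg_malformed_beat", "non-positive systolic area")
  list(total_area = sys_area + dia_area,
       systolic_area = sys_area, diastolic_area = dia_area,
       IPA = dia_area / sys_area)
}

#' Augmentation indices, stiffness index and time ratios
#'
#' The seven amplitude/time indices: AI_amp = (SA − notch_amp)/SA,
#' RI = notch_amp/SA, AI_time = PTT/pulse interval, SI = height/PTT (m/s),
#' T1 = CT/dT, T2 = systolic_time/dT, T3 = PTT/dT. Missing inputs
#' propagate: no dT (last beat) drops T1–T3; no notch drops every
#' notch-dependent index.
#'
#' @param feats named list containing `SA`, `notch_amp`, `PTT`,
#'   `pulse_interval`, `CT`, `systolic_time`, `dT` (as produced by the
#'   upstream feature operations).
#' @param height_m subject height (m).
#' @return named list `AI_amp`, `RI`, `AI_time`, `SI`, `T1`, `T2`, `T3`.
#' @export
indices <- function(feats, height_m) {
  stopifnot(is.finite(feats$SA), feats$SA > 0, height_m > 0)
  has_notch <- is.finite(feats$notch_amp) && is.finite(feats$PTT)
  has_dT <- is.finite(feats$dT) && feats$dT > 0
  safe_div <- function(num, den, ok) if (ok) num / den else NA_real_
  list(
    AI_amp = safe_div(feats$SA - feats$notch_amp, feats$SA, has_notch),
    RI = safe_div(feats$notch_amp, feats$SA, has_notch),
    AI_time = safe_div(feats$PTT, feats$pulse_interval,
                       has_notch && feats$pulse_interval > 0),
    SI = safe_div(height_m, feats$PTT, has_notch && feats$PTT > 0),
    T1 = safe_div(feats$CT, feats$dT, has_dT),
    T2 = safe_div(feats$systolic_time, feats$dT,
                  has_dT && is.finite(feats$systolic_time)),
    T3 = safe_div(feats$PTT, feats$dT, has_dT && has_notch)
  )
}

#' APG amplitude features and ratios
#'
#' Signed amplitudes of the a, b and e waves and the vascular-aging ratios
#' b/a, e/a and (b−e)/a. The a wave must be positive and non-zero; an
#' absent e wave leaves e and its ratios missing.
#'
#' @param apg_waves output of [detect_apg_waves()].
#' @return named list `a`, `b`, `e`, `b_over_a`, `e_over_a`,
#'   `b_minus_e_over_a`.
#' @export
apg_features <- function(apg_waves) {
  a <- apg_waves$a$amp
  b <- apg_waves$b$amp
  if (!is.finite(a) || a == 0)
    abort_ppg("ppg_malformed_beat", "APG a wave amplitude is zero")
  e <- if (is.null(apg_waves$e)) NA_real_ else apg_waves$e$amp
  list(a = a, b = b, e = e,
       b_over_a = b / a,
       e_over_a = if (is.finite(e)) e / a else NA_real_,
       b_minus_e_over_a = if (is.finite(e)) (b - e) / a else NA_real_)
}

#' All 24 features of one beat
#'
#' Orchestrates fiducial detection and the feature operations for a single
#' beat; `next_fid` supplies the cross-beat peak-to-peak interval.
#'
#' @param beat a `ppg_beat`.
#' @param fid its `fiducial_set` (computed if `NULL`).
#' @param next_fid the next consecutive beat's `fiducial_set` or `NULL`.
#' @param height_m subject height (m) for the stiffness index.
#' @return named list over [ppg_feature_names()] (`NA` where undefined).
#' @export
beat_features <- function(beat, fid = NULL, next_fid = NULL, height_m = 1.70) {
  if (is.null(fid)) fid <- beat_fiducials(beat)
  tf <- timing_features(fid, next_fid)
  aw <- amplitude_and_width(beat, fid)
  ar <- if (is.finite(fid$t_notch)) {
    tryCatch(areas(beat, fid),
             ppg_malformed_beat = function(e) list(total_area = NA_real_, IPA = NA_real_))
  } else list(total_area = NA_real_, IPA = NA_real_)
  apg <- apg_features(list(a = fid$apg_a, b = fid$apg_b, e = fid$apg_e))
  core <- c(list(SA = aw$SA, notch_amp = aw$notch_amp, PW = aw$PW), tf)
  idx <- indices(core, height_m)
  out <- c(core,
           list(total_area = ar$total_area, IPA = ar$IPA),
           idx, apg)
  out[ppg_feature_names()]
}

#' Extract per-beat features for one recording
#'
#' Filters, segments, locates fiducials and computes the feature catalogue
#' for every accepted beat. Beats that fail fiducial detection are dropped;
#' the peak-to-peak interval dT links only consecutive accepted beats
#' (pairs spanning a rejected beat are left missing).
#'
#' @param record a raw `ppg_record`.
#' @param height_m subject height (m).
#' @param spec [filter_spec()] used for preprocessing.
#' @param prefiltered set `TRUE` if `record` is already band-passed.
#' @return data frame: `subject_id`, `beat_index`, `onset_index`, one
#'   column per feature, plus `notch_present`.
#' @export
extract_beat_features <- function(record, height_m = 1.70,
                                  spec = filter_spec(fs = record$fs),
                                  prefiltered = FALSE) {
  filtered <- if (prefiltered) record else filter_record(record, spec)
  beats <- segment_beats(filtered)
  if (!length(beats)) abort_ppg("ppg_no_beats", "no beats survived segmentation")
  fids <- vector("list", length(beats))
  ok <- logical(length(beats))
  for (i in seq_along(beats)) {
    fids[[i]] <- tryCatch(beat_fiducials(beats[[i]]),
                          ppg_error = function(e) NULL)
    ok[i] <- !is.null(fids[[i]])
  }
  feats <- ppg_feature_names()
  rows <- list()
  for (i in which(ok)) {
    ## consecutive in the record: next beat starts where this one ends
    nxt <- NULL
    if (i < length(beats) && ok[i + 1L] &&
        beats[[i + 1L]]$onset_index == beats[[i]]$end_index)
      nxt <- fids[[i + 1L]]
    fl <- tryCatch(
      beat_features(beats[[i]], fid = fids[[i]], next_fid = nxt,
                    height_m = height_m),
      ppg_error = function(e) NULL)
    if (is.null(fl)) next
    rows[[length(rows) + 1L]] <- c(
      beat_index = beats[[i]]$beat_index,
      onset_index = beats[[i]]$onset_index,
      unlist(fl, use.names = FALSE),
      notch_present = is.finite(fids[[i]]$t_notch)
    )
  }
  if (!length(rows)) abort_ppg("ppg_no_beats", "no beat yielded valid features")
  mat <- do.call(rbind, rows)
  colnames(mat) <- c("beat_index", "onset_index", feats, "notch_present")
  out <- as.data.frame(mat)
  out$notch_present <- as.logical(out$notch_present)
  cbind(subject_id = record$subject_id, out)
}

#' Aggregate per-beat features to the subject level
#'
#' Per-feature sample mean and sample variance (n−1 denominator) over the
#' beats where each feature is defined, joined with the subject's
#' demographics, oximeter readings and class label. Subjects with fewer
#' than `min_beats` valid beats are excluded. The fraction of beats with a
#' detectable notch and a pulse-rate estimate derived from the mean
#' peak-to-peak interval are carried along for cross-checking.
#'
#' @param beat_df output of [extract_beat_features()].
#' @param profile one-row data frame with `subject_id`, `label`, the
#'   demographic columns, `SpO2` and `pulse_rate`.
#' @param min_beats minimum number of valid beats for inclusion.
#' @return one-row data frame: `<feature>_mean` and `<feature>_var` for
#'   every catalogue feature, demographics, `SpO2`, `pulse_rate`, `label`,
#'   `n_beats_used`, `notch_fraction`, `pulse_rate_derived`.
#' @export
aggregate_subject <- function(beat_df, profile, min_beats = 5) {
  feats <- ppg_feature_names()
  valid <- is.finite(beat_df$SA)
  n_used <- sum(valid)
  if (n_used < min_beats)
    abort_ppg("ppg_subject_excluded",
              sprintf("only %d valid beats (< %d)", n_used, min_beats))
  bd <- beat_df[valid, , drop = FALSE]
  means <- vapply(feats, function(f) sample_mean(bd[[f]]), numeric(1))
  vars <- vapply(feats, function(f) sample_var(bd[[f]]), numeric(1))
  out <- data.frame(subject_id = profile$subject_id)
  for (f in feats) out[[paste0(f, "_mean")]] <- means[[f]]
  for (f in feats) out[[paste0(f, "_var")]] <- vars[[f]]
  demo_cols <- c("age", "height", "weight", "BMI", "gender", "smoking",
                 "respiratory_problem", "blood_pressure",
                 "physical_activity", "others", "SpO2", "pulse_rate")
  for (col in demo_cols) out[[col]] <- profile[[col]]
  out$label <- profile$label
  out$n_beats_used <- n_used
  out$notch_fraction <- mean(bd$notch_present)
  dTs <- bd$dT[is.finite(bd$dT)]
  out$pulse_rate_derived <- if (length(dTs)) 60 / mean(dTs) else NA_real_
  out
}

#' Subject-level feature table for a whole cohort
#'
#' @param cohort a `ppg_cohort` from [generate_cohort()].
#' @param spec [filter_spec()] for preprocessing.
#' @param min_beats minimum valid beats per subject.
#' @return data frame, one row per included subject (see
#'   [aggregate_subject()]); excluded subjects are dropped with a warning.
#' @export
extract_cohort_features <- function(cohort, spec = NULL, min_beats = 5) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  rows <- list()
  dropped <- character(0)
  for (i in seq_len(nrow(cohort$subjects))) {
    profile <- cohort$subjects[i, , drop = FALSE]
    rec <- cohort$recordings[[profile$subject_id]]
    fspec <- if (is.null(spec)) filter_spec(fs = rec$fs) else spec
    row <- tryCatch({
      bf <- extract_beat_features(rec, height_m = profile$height, spec = fspec)
      aggregate_subject(bf, profile, min_beats = min_beats)
    }, ppg_error = function(e) NULL)
    if (is.null(row)) dropped <- c(dropped, profile$subject_id)
    else rows[[length(rows) + 1L]] <- row
  }
  if (length(dropped))
    warning("excluded ", length(dropped), " subject(s): ",
            paste(dropped, collapse = ", "))
  if (!length(rows)) abort_ppg("ppg_no_beats", "no subject yielded features")
  do.call(rbind, rows)
}
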