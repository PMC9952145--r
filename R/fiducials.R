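#' Detect the systolic peak of a beat
#'
#' The systolic peak is the highest — and, under the tie rule, the first —
#' sample of the beat. A maximum falling on the first or last sample means
#' the beat has no interior peak and is rejected as malformed.
#'
#' @param beat a `ppg_beat`.
#' @return list `t` (absolute time, s) and `amp` (raw amplitude).
#' @export
detect_systolic_peak <- function(beat) {
  stopifnot(inherits(beat, "ppg_beat"))
  x <- beat$samples
  i <- which.max(x)                      # first index on ties
  if (i == 1L || i == length(x))
    abort_ppg("ppg_malformed_beat", "systolic maximum lies on the beat boundary")
  list(t = (beat$onset_index + i - 1L) / beat$fs, amp = x[i])
}

#' Acceleration plethysmogram (APG) of a beat
#'
#' Smoothed second derivative of the pulse wave, computed with a
#' Savitzky–Golay local-polynomial filter (order 3, 11-sample window at
#' 120 Hz by default). Plain finite differences amplify noise at the
#' second-derivative level; the local polynomial keeps the a/b/e waves
#' readable. The window is shrunk (with a warning) for beats shorter than
#' the window.
#'
#' @param beat a `ppg_beat` with at least 7 samples.
#' @param window odd window length (samples).
#' @param order polynomial order.
#' @return numeric vector, same length as the beat, in a.u./s^2.
#' @export
compute_apg <- function(beat, window = 11, order = 3) {
  stopifnot(inherits(beat, "ppg_beat"))
  n <- length(beat$samples)
  if (n < 7) abort_ppg("ppg_malformed_beat", "beat too short for an APG (need >= 7 samples)")
  if (window %% 2 == 0) window <- window + 1
  if (window > n) {
    window <- if (n %% 2 == 1) n else n - 1L
    warning("APG smoothing window shrunk to ", window, " samples")
  }
  if (window < order + 2) window <- order + 2 + (order %% 2)  # smallest valid odd
  key <- paste(order, window, beat$fs, sep = "|")
  F <- .sg_cache[[key]]
  if (is.null(F)) {
    F <- signal::sgolay(p = order, n = window, m = 2, ts = 1 / beat$fs)
    .sg_cache[[key]] <- F
  }
  as.numeric(signal::sgolayfilt(beat$samples, F))
}

.sg_cache <- new.env(parent = emptyenv())

#' Detect the APG a, b and e waves
#'
#' a is the first prominent APG maximum (early systolic positive wave),
#' b the first prominent minimum after a (early systolic negative wave),
#' and e the first prominent maximum after the systolic peak — the wave
#' that marks the dicrotic notch. Prominence is thresholded at a fraction
#' of the APG range. An e candidate is accepted only if a local APG
#' minimum follows it: the dip reflects the diastolic wave's negative
#' curvature, and without it the "maximum" is just the decaying tail of a
#' single-component pulse, which has no dicrotic structure.
#'
#' @param apg output of [compute_apg()].
#' @param beat the `ppg_beat` the APG came from.
#' @param t_sys systolic peak time (s, absolute) from
#'   [detect_systolic_peak()].
#' @param prominence_frac prominence threshold as a fraction of the APG
#'   range.
#' @return list with components `a`, `b`, `e`; each is `list(t, amp)`, `e`
#'   may be `NULL` (absent).
#' @export
detect_apg_waves <- function(apg, beat, t_sys, prominence_frac = 0.05) {
  stopifnot(inherits(beat, "ppg_beat"), length(apg) == length(beat$samples))
  prom <- prominence_frac * diff(range(apg))
  if (!is.finite(prom) || prom <= 0)
    abort_ppg("ppg_malformed_beat", "degenerate APG (zero range)")
  maxima <- find_peaks(apg, min_prominence = prom)
  minima <- find_troughs(apg, min_prominence = prom)
  if (!length(maxima)) abort_ppg("ppg_malformed_beat", "no APG a wave found")
  ia <- maxima[1]
  ib_cand <- minima[minima > ia]
  if (!length(ib_cand)) abort_ppg("ppg_malformed_beat", "no APG b wave found")
  ib <- ib_cand[1]
  i_sys <- round(t_sys * beat$fs) - beat$onset_index + 1L
  ie_cand <- maxima[maxima > max(i_sys, ib)]
  ## diastolic-curvature evidence: a trough must follow the e candidate
  dips <- find_troughs(apg, min_prominence = 0.2 * prom)
  ie <- integer(0)
  for (i in ie_cand) if (any(dips > i)) { ie <- i; break }
  to_wave <- function(i) list(t = (beat$onset_index + i - 1L) / beat$fs,
                              amp = apg[i])
  list(a = to_wave(ia), b = to_wave(ib),
       e = if (length(ie)) to_wave(ie) else NULL)
}

#' Detect the dicrotic notch
#'
#' Primary rule: the lowest local minimum of the pulse wave within 40% of
#' the pulse interval after the systolic peak. In stiff-artery and CVD
#' pulses the diastolic wave can degrade to a shoulder with no local
#' minimum; then the APG e wave — which marks the notch — is used as a
#' fallback. If both fail the notch is absent, a valid outcome: notch-
#' dependent features are simply missing for that beat.
#'
#' @param beat a `ppg_beat`.
#' @param t_sys systolic peak time (s, absolute).
#' @param apg_waves output of [detect_apg_waves()] (may be `NULL` to skip
#'   the fallback).
#' @param window_frac notch search window as a fraction of the pulse
#'   interval after the peak.
#' @return list `t`, `amp`, `source` (one of `"derivative-minimum"`,
#'   `"apg-e-wave"`), or `NULL` when absent.
#' @export
detect_dicrotic_notch <- function(beat, t_sys, apg_waves = NULL,
                                  window_frac = 0.4) {
  stopifnot(inherits(beat, "ppg_beat"))
  x <- beat$samples
  fs <- beat$fs
  n <- length(x)
  pulse_interval <- n / fs
  i_sys <- round(t_sys * fs) - beat$onset_index + 1L
  i_hi <- min(n - 1L, i_sys + ceiling(window_frac * pulse_interval * fs))
  if (i_hi - i_sys >= 2) {
    seg <- x[(i_sys + 1L):i_hi]
    ## prominence floor rejects micro-minima left by filter ripple
    mins <- find_troughs(seg, min_prominence = 0.005 * diff(range(x)))
    if (length(mins)) {
      im <- mins[which.min(seg[mins])] + i_sys
      return(list(t = (beat$onset_index + im - 1L) / fs, amp = x[im],
                  source = "derivative-minimum"))
    }
  }
  if (!is.null(apg_waves) && !is.null(apg_waves$e)) {
    te <- apg_waves$e$t
    if (te > t_sys && te <= t_sys + window_frac * pulse_interval) {
      ie <- round(te * fs) - beat$onset_index + 1L
      if (ie >= 1L && ie <= n)
        return(list(t = te, amp = x[ie], source = "apg-e-wave"))
    }
  }
  NULL
}

#' Locate all landmarks of one beat
#'
#' Runs peak, APG-wave and notch detection and assembles a fiducial set.
#' Times are absolute seconds in the recording; amplitudes are raw signal
#' values (the per-beat baseline is handled by the feature layer).
#'
#' @param beat a `ppg_beat`.
#' @param apg_window,apg_order APG smoothing parameters.
#' @param notch_window_frac notch search window fraction.
#' @return object of class `fiducial_set`: `t_onset`, `t_sys`, `amp_sys`,
#'   `t_notch`/`amp_notch` (`NA` when absent), `t_end`, `apg_a`, `apg_b`,
#'   `apg_e` (`NULL` when absent), `notch_source`, `onset_amp`.
#' @export
beat_fiducials <- function(beat, apg_window = 11, apg_order = 3,
                           notch_window_frac = 0.4) {
  stopifnot(inherits(beat, "ppg_beat"))
  sys <- detect_systolic_peak(beat)
  apg <- compute_apg(beat, window = apg_window, order = apg_order)
  waves <- detect_apg_waves(apg, beat, sys$t)
  notch <- detect_dicrotic_notch(beat, sys$t, waves,
                                 window_frac = notch_window_frac)
  structure(list(
    t_onset = beat$onset_index / beat$fs,
    t_sys = sys$t, amp_sys = sys$amp,
    t_notch = if (is.null(notch)) NA_real_ else notch$t,
    amp_notch = if (is.null(notch)) NA_real_ else notch$amp,
    t_end = beat$end_index / beat$fs,
    apg_a = waves$a, apg_b = waves$b, apg_e = waves$e,
    notch_source = if (is.null(notch)) "absent" else notch$source,
    onset_amp = beat$samples[1]
  ), class = "fiducial_set")
}
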