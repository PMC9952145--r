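#' Fiducial recovery against generator ground truth
#'
#' Runs the full preprocessing + fiducial chain on each recording of a
#' cohort and matches detected beats to ground-truth beats by onset
#' proximity (within 30% of the true beat period). For each matched beat
#' it scores whether the detected systolic-peak time — and, where the
#' truth has a notch, the detected notch time — fall within
#' `tol_samples / fs` of the truth. Unmatched truth beats (typically the
#' recording edges) count as misses, so the rates are conservative.
#'
#' @param cohort a `ppg_cohort`.
#' @param tol_samples tolerance in samples.
#' @param spec [filter_spec()] for preprocessing.
#' @return list: `peak_recovery` and `notch_recovery` (fractions in 0–1),
#'   `false_notch_rate` (notches reported on systolic-only beats, i.e.
#'   beats with no diastolic component at all), `n_truth_beats`,
#'   `n_truth_notches`, `per_subject` data frame.
#' @export
fiducial_recovery <- function(cohort, tol_samples = 2, spec = NULL) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  per <- list()
  for (sid in names(cohort$recordings)) {
    rec <- cohort$recordings[[sid]]
    truth <- cohort$truth[[sid]]
    fspec <- if (is.null(spec)) filter_spec(fs = rec$fs) else spec
    tol <- tol_samples / rec$fs
    res <- tryCatch({
      filtered <- filter_record(rec, fspec)
      beats <- segment_beats(filtered)
      fids <- lapply(beats, function(b)
        tryCatch(beat_fiducials(b), ppg_error = function(e) NULL))
      fids <- fids[!vapply(fids, is.null, logical(1))]
      det_onsets <- vapply(fids, `[[`, numeric(1), "t_onset")
      peak_hit <- notch_hit <- logical(nrow(truth))
      notch_truth <- truth$has_notch
      sys_only <- !truth$has_diastolic
      false_notch <- 0L
      for (i in seq_len(nrow(truth))) {
        period <- truth$t_end[i] - truth$t_onset[i]
        j <- if (length(det_onsets))
          which.min(abs(det_onsets - truth$t_onset[i])) else integer(0)
        if (!length(j) ||
            abs(det_onsets[j] - truth$t_onset[i]) > 0.3 * period) next
        fid <- fids[[j]]
        peak_hit[i] <- abs(fid$t_sys - truth$t_sys[i]) <= tol
        if (notch_truth[i]) {
          notch_hit[i] <- is.finite(fid$t_notch) &&
            abs(fid$t_notch - truth$t_notch[i]) <= tol
        } else if (sys_only[i] && is.finite(fid$t_notch)) {
          false_notch <- false_notch + 1L
        }
      }
      data.frame(subject_id = sid,
                 n_beats = nrow(truth),
                 n_notch = sum(notch_truth),
                 n_sys_only = sum(sys_only),
                 peak_hits = sum(peak_hit),
                 notch_hits = sum(notch_hit[notch_truth]),
                 false_notch = false_notch)
    }, ppg_error = function(e)
      data.frame(subject_id = sid, n_beats = nrow(truth),
                 n_notch = sum(truth$has_notch),
                 n_sys_only = sum(!truth$has_diastolic), peak_hits = 0L,
                 notch_hits = 0L, false_notch = 0L))
    per[[sid]] <- res
  }
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  n_beats <- sum(per$n_beats)
  n_notch <- sum(per$n_notch)
  n_sys_only <- sum(per$n_sys_only)
  list(
    peak_recovery = sum(per$peak_hits) / n_beats,
    notch_recovery = if (n_notch) sum(per$notch_hits) / n_notch else NA_real_,
    false_notch_rate = if (n_sys_only) sum(per$false_notch) / n_sys_only else 0,
    n_truth_beats = n_beats,
    n_truth_notches = n_notch,
    per_subject = per
  )
}
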