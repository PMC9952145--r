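#' Per-feature Welch t-test screen, healthy vs CVD
#'
#' Welch (unequal-variance) two-sample t-tests comparing each subject-level
#' feature column between the healthy group and the pooled CVD group, at a
#' 0.05 significance level. No multiple-testing correction is applied to
#' the significance flag (matching the screening protocol this mirrors); a
#' Benjamini–Hochberg adjusted column is included for honest reading.
#'
#' @param data subject-level feature table with a `label` column.
#' @param features columns to test; defaults to all numeric feature columns.
#' @param alpha significance level.
#' @return data frame sorted by p-value: `feature`, `t_statistic`,
#'   `p_value`, `mean_healthy`, `mean_cvd`, `significant`, `p_bh`.
#' @export
ttest_features <- function(data, features = NULL, alpha = 0.05) {
  if (!"label" %in% names(data))
    abort_ppg("ppg_schema_error", "data must carry a label column")
  healthy <- data$label == "Healthy"
  if (!any(healthy) || all(healthy))
    abort_ppg("ppg_schema_error", "need both healthy and CVD rows")
  if (is.null(features)) {
    drop_cols <- c("subject_id", "label", "n_beats_used")
    features <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                        drop_cols)
  }
  rows <- list()
  for (f in features) {
    g1 <- data[[f]][healthy]; g1 <- g1[is.finite(g1)]
    g2 <- data[[f]][!healthy]; g2 <- g2[is.finite(g2)]
    if (length(g1) < 2 || length(g2) < 2) {
      warning("skipping '", f, "': fewer than 2 values in a group")
      next
    }
    v1 <- stats::var(g1); v2 <- stats::var(g2)
    if (v1 + v2 == 0) {
      ## t.test refuses constant data; the null is then exactly decidable
      tt <- list(statistic = if (mean(g1) == mean(g2)) 0 else Inf,
                 p.value = if (mean(g1) == mean(g2)) 1 else 0)
    } else {
      ht <- stats::t.test(g1, g2, var.equal = FALSE)
      tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      feature = f, t_statistic = tt$statistic, p_value = tt$p.value,
      mean_healthy = mean(g1), mean_cvd = mean(g2),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(feature = character(0), t_statistic = numeric(0),
                      p_value = numeric(0), mean_healthy = numeric(0),
                      mean_cvd = numeric(0), significant = logical(0),
                      p_bh = numeric(0)))
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < alpha
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render selection / accuracy / t-test tables to files
#'
#' Writes the per-classifier selected-feature table, the per-classifier
#' accuracy table (with per-class and macro recall), the t-test screen and
#' the confusion matrices as CSV files, plus a plain-text summary.
#' Regeneration from the same inputs is byte-identical.
#'
#' @param selection_results named list (by classifier) of
#'   `selection_result` objects; may be `NULL`.
#' @param evaluation_reports named list (by classifier) of
#'   `classification_report` objects; may be `NULL`.
#' @param ttest_results output of [ttest_features()]; may be `NULL`.
#' @param out_dir output directory (created if needed).
#' @param stage integer tag used in the file names.
#' @return invisibly, the vector of files written.
#' @export
render_reports <- function(selection_results = NULL,
                           evaluation_reports = NULL,
                           ttest_results = NULL,
                           out_dir, stage = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if (!is.null(selection_results)) {
    sel <- data.frame(
      classifier = names(selection_results),
      selected_features = vapply(selection_results, function(s)
        paste(s$selected_features, collapse = "; "), character(1)),
      n_selected = vapply(selection_results, function(s)
        length(s$selected_features), numeric(1)),
      cv_accuracy = vapply(selection_results, function(s)
        s$final_cv_accuracy, numeric(1)),
      stringsAsFactors = FALSE)
    f <- file.path(out_dir, sprintf("selection_stage%d.csv", stage))
    utils::write.csv(sel, f, row.names = FALSE)
    written <- c(written, f)
  }
  if (!is.null(evaluation_reports)) {
    acc <- data.frame(
      classifier = names(evaluation_reports),
      accuracy = vapply(evaluation_reports, function(r) r$accuracy, numeric(1)),
      macro_recall = vapply(evaluation_reports, function(r)
        r$macro_recall, numeric(1)),
      stringsAsFactors = FALSE)
    f <- file.path(out_dir, sprintf("accuracy_stage%d.csv", stage))
    utils::write.csv(acc, f, row.names = FALSE)
    written <- c(written, f)
    for (nm in names(evaluation_reports)) {
      f <- file.path(out_dir, sprintf("confusion_stage%d_%s.csv", stage, nm))
      utils::write.csv(as.data.frame.matrix(evaluation_reports[[nm]]$confusion),
                       f, row.names = TRUE)
      written <- c(written, f)
    }
  }
  if (!is.null(ttest_results)) {
    f <- file.path(out_dir, "ttests.csv")
    utils::write.csv(ttest_results, f, row.names = FALSE)
    written <- c(written, f)
  }
  invisible(written)
}
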