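#' Rebalance classes by whole-subject replication
#'
#' Minority classes are replicated whole-subject-wise: each class with
#' n_c < n_max is stacked ceiling(n_max/n_c) times, then truncated to
#' n_max rows (deterministic row order). `replicate-train-only` defers the
#' replication to the training partition of each cross-validation fold
#' (leak-free); `replicate-global` balances the whole table up front, which
#' lets duplicates of one subject fall on both sides of a fold split —
#' provided for comparability with evaluation protocols that balance before
#' cross-validation.
#'
#' @param data data frame with a `label` column.
#' @param mode `"replicate-train-only"` or `"replicate-global"`; this
#'   function performs the replication itself (callers decide when).
#' @return the rebalanced data frame (row-bound replicates).
#' @export
balance_classes <- function(data, mode = c("replicate-train-only",
                                           "replicate-global")) {
  mode <- match.arg(mode)
  counts <- table(data$label)
  if (length(counts) < 2)
    abort_ppg("ppg_balance_error", "need at least two classes to balance")
  n_max <- max(counts)
  out <- list()
  for (cls in names(counts)) {
    rows <- data[data$label == cls, , drop = FALSE]
    reps <- ceiling(n_max / nrow(rows))
    stacked <- rows[rep(seq_len(nrow(rows)), reps), , drop = FALSE]
    out[[cls]] <- stacked[seq_len(n_max), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Stratified fold assignment: within each class, shuffled indices are
## dealt round-robin across folds.
make_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

## Training-fold median imputation applied to train and test alike.
impute_median <- function(train, test) {
  for (col in names(train)) {
    med <- stats::median(train[[col]], na.rm = TRUE)
    if (!is.finite(med)) med <- 0
    train[[col]][!is.finite(train[[col]])] <- med
    test[[col]][!is.finite(test[[col]])] <- med
  }
  list(train = train, test = test)
}

#' Stratified k-fold cross-validated accuracy
#'
#' Deterministic given the seed: folds are stratified by class, missing
#' values are imputed with training-fold medians, and (in leak-free mode)
#' minority-class replication happens inside each training fold only.
#'
#' @param data data frame with `label`, optionally `subject_id`, and the
#'   feature columns.
#' @param feature_subset character vector of feature columns to use.
#' @param spec a [classifier_spec()].
#' @param k number of folds.
#' @param seed integer seed for fold assignment and stochastic fits.
#' @param balance balancing mode, or `"none"`.
#' @return accuracy in percent.
#' @export
cv_accuracy <- function(data, feature_subset, spec, k = 10, seed = 1L,
                        balance = c("replicate-train-only",
                                    "replicate-global", "none")) {
  balance <- match.arg(balance)
  if (!length(feature_subset))
    abort_ppg("ppg_config_error", "feature subset must be non-empty")
  missing_f <- setdiff(feature_subset, names(data))
  if (length(missing_f))
    abort_ppg("ppg_schema_error",
              paste("unknown features:", paste(missing_f, collapse = ", ")))
  res <- cv_predictions(data, feature_subset, spec, k, seed, balance)
  100 * mean(res$pred == res$truth)
}

## Shared CV engine: returns pooled out-of-fold predictions plus the fold
## bookkeeping the leakage audit and the report layer need.
cv_predictions <- function(data, feature_subset, spec, k, seed, balance) {
  set.seed(seed)
  data$label <- droplevels(as.factor(data$label))
  if (balance == "replicate-global") data <- balance_classes(data)
  counts <- table(data$label)
  if (any(counts < k))
    abort_ppg("ppg_fold_error",
              sprintf("class '%s' has %d members, fewer than k = %d; balance first",
                      names(counts)[which.min(counts)], min(counts), k))
  fold <- make_folds(data$label, k)
  preds <- factor(rep(NA_character_, nrow(data)), levels = levels(data$label))
  fold_subjects <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- data[fold != f, , drop = FALSE]
    te <- data[fold == f, , drop = FALSE]
    if (balance == "replicate-train-only") tr <- balance_classes(tr)
    imp <- impute_median(tr[, feature_subset, drop = FALSE],
                         te[, feature_subset, drop = FALSE])
    model <- fit_classifier(spec, imp$train, tr$label)
    preds[fold == f] <- predict(model, imp$test)
    fold_subjects[[f]] <- list(
      train = unique(as.character(tr$subject_id)),
      test = unique(as.character(te$subject_id))
    )
  }
  list(pred = preds, truth = data$label, fold = fold,
       fold_subjects = fold_subjects)
}

#' Audit cross-validation folds for subject leakage
#'
#' Re-runs the fold construction of [cv_accuracy()] and counts subject
#' identifiers appearing in both the training and test partition of any
#' fold. In `replicate-train-only` mode the count must be zero; in
#' `replicate-global` mode duplicated minority subjects typically leak.
#'
#' @inheritParams cv_accuracy
#' @return list `shared_ids` (character vector of leaked subject ids) and
#'   `n_shared` (count).
#' @export
audit_fold_leakage <- function(data, feature_subset, spec, k = 10, seed = 1L,
                               balance = "replicate-train-only") {
  res <- cv_predictions(data, feature_subset, spec, k, seed, balance)
  shared <- character(0)
  for (fs in res$fold_subjects)
    shared <- union(shared, intersect(fs$train, fs$test))
  list(shared_ids = shared, n_shared = length(shared))
}

#' Greedy stepwise wrapper feature selection
#'
#' Forward search starts from the empty set and at each step adds the
#' feature whose addition maximizes the cross-validated accuracy of the
#' wrapped classifier, stopping when no addition improves by more than
#' `tol`; backward search starts from the full set and removes
#' symmetrically. Ties are broken by candidate order (the feature
#' declaration order), so the search is deterministic given the seed.
#'
#' @param data data frame with `label` and candidate feature columns.
#' @param spec a [classifier_spec()] (the wrapped classifier).
#' @param candidates character vector of candidate features; defaults to
#'   every numeric column except identifiers.
#' @param direction `"forward"` or `"backward"`.
#' @param k CV folds.
#' @param seed integer seed (same folds are reused across all candidate
#'   evaluations, so accuracies are comparable).
#' @param tol minimum accuracy improvement (percentage points) to accept a
#'   step.
#' @param balance balancing mode passed to [cv_accuracy()].
#' @return object of class `selection_result`: `selected_features`,
#'   `accuracy_trajectory` (percent, per accepted step), `direction`,
#'   `final_cv_accuracy`, `baseline_accuracy`.
#' @export
greedy_stepwise_select <- function(data, spec, candidates = NULL,
                                   direction = c("forward", "backward"),
                                   k = 10, seed = 1L, tol = 0,
                                   balance = "replicate-train-only") {
  direction <- match.arg(direction)
  if (is.null(candidates)) {
    drop_cols <- c("subject_id", "label", "n_beats_used")
    candidates <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          drop_cols)
  }
  if (length(candidates) < 2)
    abort_ppg("ppg_config_error", "need at least two candidate features")
  acc_of <- function(subset) cv_accuracy(data, subset, spec, k = k,
                                         seed = seed, balance = balance)
  counts <- table(droplevels(as.factor(data$label)))
  baseline <- 100 * max(counts) / sum(counts)
  trajectory <- numeric(0)
  if (direction == "forward") {
    current <- character(0)
    current_acc <- baseline
    repeat {
      remaining <- setdiff(candidates, current)
      if (!length(remaining)) break
      accs <- vapply(remaining, function(f) acc_of(c(current, f)), numeric(1))
      best <- which.max(accs)                 # first index on ties
      if (accs[best] > current_acc + tol) {
        current <- c(current, remaining[best])
        current_acc <- accs[best]
        trajectory <- c(trajectory, current_acc)
      } else break
    }
  } else {
    current <- candidates
    current_acc <- acc_of(current)
    trajectory <- current_acc
    while (length(current) > 1) {
      accs <- vapply(current, function(f) acc_of(setdiff(current, f)),
                     numeric(1))
      best <- which.max(accs)
      if (accs[best] > current_acc + tol) {
        current <- setdiff(current, current[best])
        current_acc <- accs[best]
        trajectory <- c(trajectory, current_acc)
      } else break
    }
  }
  structure(list(selected_features = current,
                 accuracy_trajectory = trajectory,
                 direction = direction,
                 final_cv_accuracy = current_acc,
                 baseline_accuracy = baseline),
            class = "selection_result")
}

## ---- two-stage cascade ---------------------------------------------------

#' Default feature columns for each cascade stage
#'
#' Stage 1 uses per-feature means and variances plus demographics; stage 2
#' uses means only plus demographics.
#'
#' @param data subject-level feature table.
#' @return character vector of column names present in `data`.
#' @export
stage1_feature_cols <- function(data) {
  feats <- ppg_feature_names()
  cols <- c(paste0(feats, "_mean"), paste0(feats, "_var"),
            c("age", "height", "weight", "BMI", "gender", "smoking",
              "respiratory_problem", "blood_pressure", "physical_activity",
              "others", "SpO2", "pulse_rate"))
  intersect(cols, names(data))
}

#' @rdname stage1_feature_cols
#' @export
stage2_feature_cols <- function(data) {
  feats <- ppg_feature_names()
  cols <- c(paste0(feats, "_mean"),
            c("age", "height", "weight", "BMI", "gender", "smoking",
              "respiratory_problem", "blood_pressure", "physical_activity",
              "others", "SpO2", "pulse_rate"))
  intersect(cols, names(data))
}

#' Fit the stage-1 (healthy vs CVD) classifier
#'
#' Stage 1 is a binary screen on per-feature means and variances plus
#' demographics; every non-Healthy label is collapsed to `"CVD"`.
#'
#' @param data subject-level feature table (see
#'   [extract_cohort_features()]).
#' @param spec a [classifier_spec()].
#' @param features feature columns; defaults to all mean + variance PPG
#'   features and demographics.
#' @return a `ppg_model` whose levels are `Healthy`/`CVD`.
#' @export
fit_stage1 <- function(data, spec, features = stage1_feature_cols(data)) {
  if (!"label" %in% names(data))
    abort_ppg("ppg_schema_error", "data must carry a label column")
  y <- factor(ifelse(data$label == "Healthy", "Healthy", "CVD"),
              levels = c("Healthy", "CVD"))
  x <- data[, features, drop = FALSE]
  imp <- impute_median(x, x)
  fit_classifier(spec, imp$train, y)
}

#' Fit the stage-2 (five-way CVD typing) classifier
#'
#' Stage 2 types the disease among CVD subjects only, on per-feature means
#' (no variance columns — the wider five-class search space uses the mean
#' value only) plus demographics. Healthy rows and variance columns are
#' schema violations, not silently dropped.
#'
#' @param data subject-level feature table restricted to CVD subjects.
#' @param spec a [classifier_spec()].
#' @param features feature columns; defaults to mean-only PPG features and
#'   demographics.
#' @param balance if `TRUE`, minority classes are replicated to the
#'   majority count before fitting.
#' @return a `ppg_model` over the five CVD labels.
#' @export
fit_stage2 <- function(data, spec, features = stage2_feature_cols(data),
                       balance = TRUE) {
  if (any(data$label == "Healthy"))
    abort_ppg("ppg_schema_error", "stage 2 is defined on CVD subjects only")
  if (any(grepl("_var$", features)))
    abort_ppg("ppg_schema_error", "stage 2 uses mean-only features, no variances")
  if (balance) data <- balance_classes(data)
  x <- data[, features, drop = FALSE]
  imp <- impute_median(x, x)
  fit_classifier(spec, imp$train, droplevels(as.factor(data$label)))
}

#' Predict through the two-stage cascade
#'
#' Subjects the stage-1 screen calls Healthy stay Healthy; the rest are
#' typed by the stage-2 model.
#'
#' @param newdata subject-level feature rows.
#' @param model1 stage-1 `ppg_model`.
#' @param model2 stage-2 `ppg_model`.
#' @return factor over `Healthy` plus the stage-2 levels.
#' @export
predict_two_stage <- function(newdata, model1, model2) {
  x1 <- newdata[, model1$features, drop = FALSE]
  x1 <- impute_median(x1, x1)$train
  s1 <- predict(model1, x1)
  out <- factor(rep("Healthy", nrow(newdata)),
                levels = c("Healthy", model2$levels))
  cvd <- which(s1 != "Healthy")
  if (length(cvd)) {
    x2 <- newdata[cvd, model2$features, drop = FALSE]
    x2 <- impute_median(x2, x2)$train
    out[cvd] <- as.character(predict(model2, x2))
  }
  out
}

#' Cross-validated evaluation of one stage
#'
#' Runs the stage's stratified k-fold CV and assembles a classification
#' report: overall accuracy, per-class and macro-averaged recall, pooled
#' out-of-fold confusion matrix and the fold assignment.
#'
#' @param data subject-level feature table (stage 1: full cohort; stage 2:
#'   CVD subjects only).
#' @param spec a [classifier_spec()].
#' @param stage 1 or 2.
#' @param features feature columns; stage defaults as in [fit_stage1()] /
#'   [fit_stage2()].
#' @param k CV folds.
#' @param seed integer seed.
#' @param balance balancing mode (see [cv_accuracy()]).
#' @return object of class `classification_report`: `accuracy` (%),
#'   `recall` (per class), `macro_recall`, `confusion` (rows = truth),
#'   `fold`, `seed`.
#' @export
evaluate_stage <- function(data, spec, stage = 1, features = NULL,
                           k = 10, seed = 1L,
                           balance = "replicate-train-only") {
  if (stage == 1) {
    if (is.null(features)) features <- stage1_feature_cols(data)
    data$label <- factor(ifelse(data$label == "Healthy", "Healthy", "CVD"),
                         levels = c("Healthy", "CVD"))
  } else {
    if (any(data$label == "Healthy"))
      abort_ppg("ppg_schema_error", "stage 2 is defined on CVD subjects only")
    if (is.null(features)) features <- stage2_feature_cols(data)
  }
  res <- cv_predictions(data, features, spec, k, seed, balance)
  confusion <- table(truth = res$truth, predicted = res$pred)
  recall <- diag(confusion) / rowSums(confusion)
  structure(list(
    accuracy = 100 * sum(diag(confusion)) / sum(confusion),
    recall = recall,
    macro_recall = mean(recall),
    confusion = confusion,
    fold = res$fold,
    seed = seed
  ), class = "classification_report")
}
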