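test_that("class replication follows the ceiling-then-truncate rule", {
  d <- data.frame(subject_id = sprintf("S%02d", 1:60),
                  label = rep(c("A", "B"), c(50, 10)), x = rnorm(60))
  b <- balance_classes(d)
  expect_equal(unname(table(b$label)["A"]), 50)
  expect_equal(unname(table(b$label)["B"]), 50)
  # each B subject appears exactly 5 times
  expect_true(all(table(b$subject_id[b$label == "B"]) == 5))
  # already balanced data is unchanged (up to row order)
  d2 <- data.frame(subject_id = sprintf("S%02d", 1:20),
                   label = rep(c("A", "B"), each = 10), x = rnorm(20))
  b2 <- balance_classes(d2)
  expect_equal(nrow(b2), 20)
  expect_equal(sort(b2$subject_id), sort(d2$subject_id))
  # {A:7, B:3}: B stacked 3x then truncated to 7
  d3 <- data.frame(subject_id = sprintf("S%02d", 1:10),
                   label = rep(c("A", "B"), c(7, 3)), x = rnorm(10))
  b3 <- balance_classes(d3)
  expect_equal(unname(table(b3$label)["B"]), 7)
  expect_error(balance_classes(d3[d3$label == "A", ]),
               class = "ppg_balance_error")
})

test_that("cross-validated accuracy is exact on separable data and deterministic", {
  set.seed(1)
  n <- 80
  y <- factor(rep(c("A", "B"), each = n / 2))
  d <- data.frame(subject_id = sprintf("S%03d", 1:n), label = y,
                  x1 = rnorm(n, ifelse(y == "A", 0, 8)), x2 = rnorm(n))
  a1 <- cv_accuracy(d, c("x1", "x2"), classifier_spec("nb"), k = 10, seed = 5)
  expect_equal(a1, 100)
  a2 <- cv_accuracy(d, c("x1", "x2"), classifier_spec("nb"), k = 10, seed = 5)
  expect_identical(a1, a2)
})

test_that("label-independent features give chance-level k-NN accuracy", {
  set.seed(42)
  n <- 200
  d <- data.frame(subject_id = sprintf("S%03d", 1:n),
                  label = factor(rep(c("A", "B"), each = n / 2)),
                  x1 = rnorm(n), x2 = rnorm(n))
  acc <- cv_accuracy(d, c("x1", "x2"), classifier_spec("knn"), k = 10,
                     seed = 9)
  # 3 sigma binomial band around 50%
  expect_lt(abs(acc - 50), 300 * sqrt(0.25 / n))
})

test_that("classes smaller than k are a fold error", {
  d <- data.frame(subject_id = sprintf("S%02d", 1:25),
                  label = rep(c("A", "B"), c(20, 5)), x1 = rnorm(25))
  expect_error(cv_accuracy(d, "x1", classifier_spec("nb"), k = 10, seed = 1,
                           balance = "none"),
               class = "ppg_fold_error")
})

test_that("greedy forward search finds a planted feature first", {
  set.seed(31)
  d <- planted_dataset(n = 100, n_noise = 10, effect = 4)
  sel <- greedy_stepwise_select(d, classifier_spec("nb"),
                                candidates = setdiff(names(d),
                                                     c("subject_id", "label")),
                                direction = "forward", k = 10, seed = 2)
  expect_equal(sel$selected_features[1], "signal")
  expect_true(all(diff(sel$accuracy_trajectory) >= 0))
  expect_gte(sel$accuracy_trajectory[1], 95)
})

test_that("uninformative candidates yield an empty selection at baseline", {
  # constant features make every wrapped classifier predict the majority
  # class, so no addition can improve on the baseline
  n <- 60
  d <- data.frame(subject_id = sprintf("S%03d", 1:n),
                  label = factor(rep(c("A", "B"), c(40, 20))),
                  flat1 = rep(1, n), flat2 = rep(2, n), flat3 = rep(3, n))
  sel <- greedy_stepwise_select(d, classifier_spec("nb"),
                                candidates = c("flat1", "flat2", "flat3"),
                                direction = "forward", k = 10, seed = 3,
                                balance = "none")
  expect_length(sel$selected_features, 0)
  expect_equal(sel$baseline_accuracy, 100 * 40 / 60)
  expect_equal(sel$final_cv_accuracy, sel$baseline_accuracy)
})

test_that("backward search keeps a sufficient subset on separable data", {
  set.seed(8)
  d <- planted_dataset(n = 60, n_noise = 3, effect = 6)
  sel <- greedy_stepwise_select(d, classifier_spec("nb"),
                                candidates = setdiff(names(d),
                                                     c("subject_id", "label")),
                                direction = "backward", k = 10, seed = 4)
  expect_true("signal" %in% sel$selected_features ||
                sel$final_cv_accuracy >= 95)
  expect_s3_class(sel, "selection_result")
})

## small extracted cohort reused by the stage tests
local({
  cfg <- noise_free_config(n_per_class = c(Healthy = 8, ACS = 8, CVA = 6,
                                           DVT = 6, HF = 5, AF = 5),
                           duration = 15, seed = 77)
  coh <- generate_cohort(cfg)
  sf <- extract_cohort_features(coh)

  test_that("stage-1 and stage-2 schemas are enforced", {
    spec <- classifier_spec("nb")
    m1 <- fit_stage1(sf, spec)
    expect_setequal(m1$levels, c("Healthy", "CVD"))
    cvd <- sf[sf$label != "Healthy", ]
    expect_error(fit_stage2(sf, spec), class = "ppg_schema_error")
    expect_error(fit_stage2(cvd, spec,
                            features = c("SA_mean", "SA_var", "age")),
                 class = "ppg_schema_error")
    m2 <- fit_stage2(cvd, spec)
    expect_false(any(grepl("_var$", m2$features)))
    expect_setequal(m2$levels, c("ACS", "CVA", "DVT", "HF", "AF"))
    # training-set accuracy beats the majority baseline
    x2 <- cvd[, m2$features, drop = FALSE]
    x2 <- ppgscreen:::impute_median(x2, x2)$train
    acc <- mean(predict(m2, x2) == cvd$label)
    expect_gte(acc, max(table(cvd$label)) / nrow(cvd))
  })

  test_that("the cascade routes stage-1 negatives straight to Healthy", {
    spec <- classifier_spec("nb")
    m1 <- fit_stage1(sf, spec)
    m2 <- fit_stage2(sf[sf$label != "Healthy", ], spec)
    pred <- predict_two_stage(sf, m1, m2)
    expect_true(all(levels(pred) == c("Healthy", m2$levels)))
    # wherever stage 1 says Healthy the cascade must say Healthy
    x1 <- sf[, m1$features, drop = FALSE]
    x1 <- ppgscreen:::impute_median(x1, x1)$train
    s1 <- predict(m1, x1)
    expect_true(all(pred[s1 == "Healthy"] == "Healthy"))
  })

  test_that("evaluation reports are internally consistent", {
    spec <- classifier_spec("nb")
    rep1 <- evaluate_stage(sf, spec, stage = 1, k = 5, seed = 2)
    expect_equal(rep1$accuracy,
                 100 * sum(diag(rep1$confusion)) / sum(rep1$confusion))
    counts <- table(ifelse(sf$label == "Healthy", "Healthy", "CVD"))
    expect_equal(unname(rowSums(rep1$confusion)),
                 as.vector(counts[rownames(rep1$confusion)]))
    expect_true(all(rep1$recall >= 0 & rep1$recall <= 1))
    expect_equal(rep1$macro_recall, mean(rep1$recall))
  })

  test_that("leak-free folds share no subjects between train and test", {
    spec <- classifier_spec("nb")
    cvd <- sf[sf$label != "Healthy", ]
    audit <- audit_fold_leakage(cvd, stage2_feature_cols(cvd), spec, k = 4,
                                seed = 3, balance = "replicate-train-only")
    expect_equal(audit$n_shared, 0)
    # global replication leaks duplicated minority-class subjects
    audit_g <- audit_fold_leakage(cvd, stage2_feature_cols(cvd), spec, k = 4,
                                  seed = 3, balance = "replicate-global")
    expect_gt(audit_g$n_shared, 0)
  })
})
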