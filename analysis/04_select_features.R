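#!/usr/bin/env Rscript
# Greedy stepwise wrapper feature selection, per classifier, for both
# cascade stages. Stage 1 (healthy vs CVD) searches over mean + variance
# PPG features plus demographics; stage 2 (five-way CVD typing) over mean
# PPG features plus demographics, CVD subjects only. Leak-free balancing
# (replication inside training folds).

library(ppgscreen)

sf <- read.csv("results/subject_features.csv")
seed <- 20260925L
classifiers <- c("nb", "j48", "rf", "jrip", "part", "mlp", "knn")

# the wrapper evaluates hundreds of candidate subsets, so the two costly
# learners run with lighter search-time settings (fewer trees / epochs);
# the final evaluation script uses the full defaults
search_params <- list(rf = list(ntree = 50),
                      mlp = list(maxit = 150, size = 8))

run_stage <- function(data, candidates, stage) {
  sel <- list()
  for (alg in classifiers) {
    t0 <- Sys.time()
    params <- if (alg %in% names(search_params)) search_params[[alg]] else list()
    sel[[alg]] <- greedy_stepwise_select(
      data, classifier_spec(alg, params = params, seed = seed),
      candidates = candidates, direction = "forward", k = 10, seed = seed)
    cat(sprintf("stage %d  %-5s acc %5.1f%%  features: %s  (%.0f s)\n",
                stage, alg, sel[[alg]]$final_cv_accuracy,
                paste(sel[[alg]]$selected_features, collapse = ", "),
                difftime(Sys.time(), t0, units = "secs")))
  }
  sel
}

cat("== Stage 1: healthy vs CVD ==\n")
s1 <- sf
s1$label <- ifelse(s1$label == "Healthy", "Healthy", "CVD")
sel1 <- run_stage(s1, stage1_feature_cols(sf), 1)
render_reports(selection_results = sel1, out_dir = "results/reports",
               stage = 1)

cat("== Stage 2: five-way CVD typing ==\n")
cvd <- sf[sf$label != "Healthy", ]
sel2 <- run_stage(cvd, stage2_feature_cols(cvd), 2)
render_reports(selection_results = sel2, out_dir = "results/reports",
               stage = 2)

saveRDS(list(stage1 = sel1, stage2 = sel2), "scratch/selection.rds")
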