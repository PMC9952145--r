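#' Classifier specification
#'
#' The seven classifier families used by the screening pipeline: a pruned
#' C4.5-style decision tree (`"j48"`, via rpart), random forest (`"rf"`,
#' 100 trees), a RIPPER-style sequential-covering rule learner (`"jrip"`),
#' a PART-style rule learner built from repeated partial trees (`"part"`),
#' a one-hidden-layer multilayer perceptron (`"mlp"`, via nnet), k-nearest
#' neighbour (`"knn"`, k = 1 on standardized features) and Gaussian naive
#' Bayes (`"nb"`, with per-class variance smoothing). Defaults are stored
#' on the spec and can be overridden through `params`.
#'
#' @param algorithm one of `"nb"`, `"j48"`, `"rf"`, `"jrip"`, `"part"`,
#'   `"mlp"`, `"knn"`.
#' @param params named list of hyperparameter overrides.
#' @param seed integer seed used by stochastic fits (rf, mlp).
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(algorithm = c("nb", "j48", "rf", "jrip", "part",
                                          "mlp", "knn"),
                            params = list(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    nb   = list(var_smoothing = 1e-9),
    j48  = list(minbucket = 2, cp = 0.01),
    rf   = list(ntree = 100),
    jrip = list(max_rules = 40, min_precision = 0.5, n_thresholds = 16),
    part = list(max_rules = 40, n_thresholds = 16),
    mlp  = list(size = NA, maxit = 500, decay = 1e-3),
    knn  = list(k = 1)
  )
  defaults[names(params)] <- params
  structure(list(algorithm = algorithm, params = defaults,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

## Standardization fitted on training data only (MLP, k-NN).
fit_scaler <- function(x) {
  mu <- vapply(x, mean, numeric(1))
  sd <- vapply(x, stats::sd, numeric(1))
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}

apply_scaler <- function(scaler, x) {
  as.data.frame(Map(function(col, m, s) (col - m) / s, x, scaler$mu, scaler$sd),
                check.names = FALSE)
}

#' Fit a classifier
#'
#' @param spec a [classifier_spec()].
#' @param x data frame of numeric features (training rows).
#' @param y factor of class labels, same length.
#' @return object of class `ppg_model` carrying the fitted model, feature
#'   list, class levels and any preprocessing state.
#' @export
fit_classifier <- function(spec, x, y) {
  stopifnot(inherits(spec, "classifier_spec"), is.data.frame(x))
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) abort_ppg("ppg_balance_error", "need at least 2 classes")
  if (!all(vapply(x, is.numeric, logical(1))))
    abort_ppg("ppg_schema_error", "all features must be numeric")
  if (anyNA(x)) abort_ppg("ppg_schema_error", "features contain NA; impute first")
  p <- spec$params
  set.seed(spec$seed)
  model <- scaler <- NULL
  alg <- spec$algorithm
  if (alg == "nb") {
    model <- e1071::naiveBayes(x, y)
    ## variance smoothing: floor each per-class sd so constant-in-class
    ## features cannot produce degenerate densities
    floor_sd <- sqrt(p$var_smoothing) +
      1e-4 * stats::median(vapply(x, stats::sd, numeric(1)), na.rm = TRUE)
    model$tables <- lapply(model$tables, function(tab) {
      tab[, 2] <- pmax(tab[, 2], floor_sd, na.rm = TRUE)
      tab[is.na(tab[, 2]), 2] <- floor_sd
      tab
    })
  } else if (alg == "j48") {
    d <- cbind(x, .y = y)
    model <- rpart::rpart(.y ~ ., data = d, method = "class",
                          control = rpart::rpart.control(
                            minbucket = p$minbucket, cp = p$cp, xval = 0))
  } else if (alg == "rf") {
    model <- randomForest::randomForest(x, y, ntree = p$ntree)
  } else if (alg == "mlp") {
    scaler <- fit_scaler(x)
    xs <- apply_scaler(scaler, x)
    size <- p$size
    if (is.na(size)) size <- min(20L, max(2L, ceiling((ncol(x) + nlevels(y)) / 2)))
    d <- cbind(xs, .y = y)
    model <- nnet::nnet(.y ~ ., data = d, size = size, maxit = p$maxit,
                        decay = p$decay, trace = FALSE, MaxNWts = 5000)
  } else if (alg == "knn") {
    scaler <- fit_scaler(x)
    model <- list(train = as.matrix(apply_scaler(scaler, x)), y = y, k = p$k)
  } else if (alg == "jrip") {
    model <- rule_learner_fit(x, y, style = "ripper",
                              max_rules = p$max_rules,
                              min_precision = p$min_precision,
                              n_thresholds = p$n_thresholds)
  } else if (alg == "part") {
    model <- rule_learner_fit(x, y, style = "part",
                              max_rules = p$max_rules,
                              min_precision = 0,
                              n_thresholds = p$n_thresholds)
  }
  structure(list(spec = spec, model = model, scaler = scaler,
                 features = names(x), levels = levels(y)),
            class = "ppg_model")
}

#' Predict class labels
#'
#' @param object a `ppg_model`.
#' @param newdata data frame containing at least the training features.
#' @param ... unused.
#' @return factor of predicted labels with the training levels.
#' @export
predict.ppg_model <- function(object, newdata, ...) {
  missing_f <- setdiff(object$features, names(newdata))
  if (length(missing_f))
    abort_ppg("ppg_schema_error",
              paste("missing features at predict time:",
                    paste(missing_f, collapse = ", ")))
  x <- newdata[, object$features, drop = FALSE]
  if (anyNA(x)) abort_ppg("ppg_schema_error", "NA in predictors; impute first")
  alg <- object$spec$algorithm
  out <- switch(alg,
    nb = stats::predict(object$model, x, type = "class"),
    j48 = stats::predict(object$model, x, type = "class"),
    rf = stats::predict(object$model, x),
    mlp = {
      xs <- apply_scaler(object$scaler, x)
      factor(stats::predict(object$model, xs, type = "class"),
             levels = object$levels)
    },
    knn = {
      xs <- as.matrix(apply_scaler(object$scaler, x))
      class::knn(object$model$train, xs, object$model$y, k = object$model$k)
    },
    jrip = rule_learner_predict(object$model, x),
    part = rule_learner_predict(object$model, x)
  )
  factor(as.character(out), levels = object$levels)
}

## ---- sequential-covering rule learner (RIPPER-style / PART-style) --------
##
## Rules are conjunctions of single-feature threshold conditions grown
## greedily to maximize Laplace-corrected precision on the still-uncovered
## training rows. RIPPER-style fixes the target class and works through
## classes from rarest to most frequent; PART-style targets the majority
## class of whatever remains (the best leaf of a partial tree).

rule_covers <- function(rule, x) {
  idx <- rep(TRUE, nrow(x))
  for (cond in rule$conds) {
    v <- x[[cond$feature]]
    idx <- idx & if (cond$op == "<=") v <= cond$threshold else v > cond$threshold
  }
  idx
}

grow_rule <- function(x, y, target, n_thresholds) {
  conds <- list()
  covered <- rep(TRUE, nrow(x))
  laplace <- function(cov) (sum(cov & y == target) + 1) / (sum(cov) + 2)
  best_prec <- laplace(covered)
  repeat {
    gain_best <- NULL
    for (f in names(x)) {
      v <- x[[f]][covered]
      if (length(unique(v)) < 2) next
      qs <- unique(stats::quantile(v, probs = seq(0.05, 0.95,
                                                  length.out = n_thresholds),
                                   names = FALSE, type = 7))
      for (thr in qs) for (op in c("<=", ">")) {
        cov <- covered & if (op == "<=") x[[f]] <= thr else x[[f]] > thr
        n_cov <- sum(cov)
        if (n_cov < 1 || n_cov == sum(covered)) next
        prec <- laplace(cov)
        if (is.null(gain_best) || prec > gain_best$prec + 1e-12) {
          gain_best <- list(feature = f, op = op, threshold = thr,
                            prec = prec, cov = cov)
        }
      }
    }
    if (is.null(gain_best) || gain_best$prec <= best_prec + 1e-12) break
    conds[[length(conds) + 1L]] <- gain_best[c("feature", "op", "threshold")]
    covered <- gain_best$cov
    best_prec <- gain_best$prec
    if (best_prec >= (sum(covered) + 1) / (sum(covered) + 2) - 1e-12) break
    if (length(conds) >= 8) break
  }
  list(conds = conds, class = target, precision = best_prec,
       coverage = sum(covered))
}

rule_learner_fit <- function(x, y, style, max_rules, min_precision,
                             n_thresholds) {
  y <- droplevels(as.factor(y))
  rules <- list()
  remaining <- rep(TRUE, nrow(x))
  counts <- sort(table(y))
  class_order <- if (style == "ripper") names(counts)[-length(counts)] else NULL
  add_rules_for <- function(target, remaining) {
    while (sum(remaining & y == target) > 0 && length(rules) < max_rules) {
      r <- grow_rule(x[remaining, , drop = FALSE], y[remaining], target,
                     n_thresholds)
      if (!length(r$conds) || r$precision < max(min_precision, 0.5)) break
      rules[[length(rules) + 1L]] <<- r
      cov <- rule_covers(r, x)
      remaining <- remaining & !cov
    }
    remaining
  }
  if (style == "ripper") {
    for (cls in class_order) remaining <- add_rules_for(cls, remaining)
  } else {
    while (any(remaining) && length(rules) < max_rules &&
           length(unique(y[remaining])) > 1) {
      target <- names(which.max(table(droplevels(y[remaining]))))
      before <- sum(remaining)
      remaining <- add_rules_for(target, remaining)
      if (sum(remaining) == before) break
    }
  }
  default <- if (any(remaining)) {
    names(which.max(table(droplevels(y[remaining]))))
  } else names(which.max(table(y)))
  list(rules = rules, default = default, levels = levels(y))
}

rule_learner_predict <- function(model, x) {
  pred <- rep(model$default, nrow(x))
  assigned <- rep(FALSE, nrow(x))
  for (r in model$rules) {
    cov <- rule_covers(r, x) & !assigned
    pred[cov] <- r$class
    assigned <- assigned | cov
  }
  factor(pred, levels = model$levels)
}
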