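# Six classifier families trained with balanced 10-fold cross-validation and
# Bayesian (Gaussian-process, expected-improvement) hyperparameter search.
# Backends are established implementations (rpart, e1071, glmnet, ranger,
# xgboost); this module owns fold construction, the optimiser, model
# comparison and probability calibration.

MODEL_FAMILIES <- c("decision_tree", "gaussian_naive_bayes",
                    "logistic_regression", "random_forest",
                    "support_vector_machine", "gradient_boosted_trees")

FHR_FEATURES <- c("basal_fhr", "accelerations", "decelerations",
                  "most_lost_beats", "stv", "high_variation_min",
                  "low_variation_min")

#' Hyperparameter search space for a classifier family
#'
#' Each parameter is described by its type (`num`/`int`), finite bounds and
#' an optional log scale. Gaussian naive Bayes has no tunable
#' hyperparameters: its space is empty and tuning returns the single point.
#'
#' @param family One of the six supported families.
#' @return Named list of parameter descriptors.
#' @export
model_search_space <- function(family) {
  family <- match.arg(family, MODEL_FAMILIES)
  switch(family,
    decision_tree = list(
      cp = list(type = "num", lo = 1e-4, hi = 0.1, log = TRUE),
      maxdepth = list(type = "int", lo = 2, hi = 20),
      minsplit = list(type = "int", lo = 5, hi = 50)),
    gaussian_naive_bayes = list(),
    logistic_regression = list(
      lambda = list(type = "num", lo = 1e-4, hi = 1, log = TRUE),
      alpha = list(type = "num", lo = 0, hi = 1)),
    random_forest = list(
      num_trees = list(type = "int", lo = 100, hi = 1000),
      mtry = list(type = "int", lo = 1, hi = 7),
      min_node_size = list(type = "int", lo = 1, hi = 20)),
    support_vector_machine = list(
      cost = list(type = "num", lo = 1e-2, hi = 1e2, log = TRUE),
      gamma = list(type = "num", lo = 1e-3, hi = 10, log = TRUE)),
    gradient_boosted_trees = list(
      eta = list(type = "num", lo = 0.01, hi = 0.3, log = TRUE),
      max_depth = list(type = "int", lo = 2, hi = 8),
      nrounds = list(type = "int", lo = 50, hi = 400),
      subsample = list(type = "num", lo = 0.5, hi = 1),
      min_child_weight = list(type = "num", lo = 1, hi = 10))
  )
}

#' Balanced cross-validation folds
#'
#' Assigns records to `k` disjoint folds balanced for outcome, gestational
#' age, trace duration and fetal sex: within each stratum, shuffled records
#' are dealt round-robin from a random starting fold, so per-fold class
#' proportions match the stratum within one record.
#'
#' @param records Cohort records.
#' @param k Number of folds.
#' @param seed Integer seed (deterministic assignment).
#' @return Integer vector of fold ids (1..k) aligned with `records`.
#' @export
make_folds <- function(records, k = 10, seed = 1) {
  counts <- table(records$cohort)
  if (length(counts) < 2 || any(counts < k)) {
    stop("validation error: need at least k = ", k, " records per class")
  }
  set.seed(seed)
  fold <- integer(nrow(records))
  for (idx in split(seq_len(nrow(records)), stratum_key(records))) {
    idx <- sample_safe(idx)
    start <- sample.int(k, 1)
    fold[idx] <- ((start + seq_along(idx) - 2L) %% k) + 1L
  }
  fold
}

#' @keywords internal
#' Fit one classifier family. X: data frame of features; y: 0/1 integer.
fit_classifier <- function(family, X, y, hp = list(), seed = 1) {
  set.seed(seed)
  yf <- factor(y, levels = c(0, 1))
  Xm <- as.matrix(X)
  switch(family,
    decision_tree = {
      ctl <- rpart::rpart.control(
        cp = hp$cp %||% 0.01,
        maxdepth = hp$maxdepth %||% 10,
        minsplit = hp$minsplit %||% 20)
      rpart::rpart(y ~ ., data = cbind(data.frame(y = yf), X),
                   method = "class", control = ctl)
    },
    gaussian_naive_bayes = e1071::naiveBayes(X, yf),
    logistic_regression = glmnet::glmnet(
      Xm, yf, family = "binomial",
      alpha = hp$alpha %||% 0.5,
      lambda = hp$lambda %||% 1e-3),
    random_forest = ranger::ranger(
      x = X, y = yf, probability = TRUE,
      num.trees = hp$num_trees %||% 500,
      mtry = min(hp$mtry %||% floor(sqrt(ncol(X))), ncol(X)),
      min.node.size = hp$min_node_size %||% 10,
      importance = "impurity",
      seed = seed, num.threads = 1),
    support_vector_machine = {
      fit <- e1071::svm(Xm, yf, kernel = "radial",
                        cost = hp$cost %||% 1,
                        gamma = hp$gamma %||% (1 / ncol(X)))
      dv <- attr(stats::predict(fit, Xm, decision.values = TRUE),
                 "decision.values")[, 1]
      attr(fit, "dv_sign") <- if (suppressWarnings(stats::cor(dv, y)) < 0) -1 else 1
      fit
    },
    gradient_boosted_trees = {
      dtrain <- xgboost::xgb.DMatrix(Xm, label = y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eta = hp$eta %||% 0.1,
                      max_depth = hp$max_depth %||% 4,
                      subsample = hp$subsample %||% 1,
                      min_child_weight = hp$min_child_weight %||% 1,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = hp$nrounds %||% 100, verbose = 0)
    },
    stop("unknown model family: ", family)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' Raw scores (probabilities, or decision values for the SVM).
score_classifier <- function(family, fit, X) {
  Xm <- as.matrix(X)
  switch(family,
    decision_tree = stats::predict(fit, X, type = "prob")[, "1"],
    gaussian_naive_bayes = stats::predict(fit, X, type = "raw")[, "1"],
    logistic_regression = as.numeric(stats::predict(fit, Xm, type = "response")),
    random_forest = stats::predict(fit, X, num.threads = 1)$predictions[, "1"],
    support_vector_machine = {
      dv <- attr(stats::predict(fit, Xm, decision.values = TRUE),
                 "decision.values")[, 1]
      attr(fit, "dv_sign") * dv
    },
    gradient_boosted_trees = stats::predict(fit, xgboost::xgb.DMatrix(Xm))
  )
}

#' Cross-validate one model configuration
#'
#' Trains on k-1 folds and scores the held-out fold, for every fold, reusing
#' a fixed fold assignment so different model families are compared on
#' identical data splits.
#'
#' @param family Classifier family.
#' @param records Training records (transformed features + `cohort`).
#' @param folds Fold ids from [make_folds()].
#' @param hp Hyperparameter list.
#' @param features Feature column names.
#' @param seed Integer seed.
#' @return List with `fold_auc` (length-k numeric), `oof_scores` and
#'   `oof_labels` (out-of-fold predictions aligned with `records`).
#' @export
cross_validate <- function(family, records, folds, hp = list(),
                           features = FHR_FEATURES, seed = 1) {
  family <- match.arg(family, MODEL_FAMILIES)
  y <- as.integer(records$cohort == "APO")
  X <- records[, features, drop = FALSE]
  k <- max(folds)
  fold_auc <- numeric(k)
  oof <- rep(NA_real_, nrow(records))
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- fit_classifier(family, X[tr, , drop = FALSE], y[tr], hp,
                          seed = seed + f)
    s <- score_classifier(family, fit, X[!tr, , drop = FALSE])
    oof[!tr] <- s
    fold_auc[f] <- auc_rank(s, y[!tr])
  }
  list(fold_auc = fold_auc, oof_scores = oof, oof_labels = y, family = family,
       hp = hp, folds = folds)
}

#' @keywords internal
#' Decode a unit-cube point into a named hyperparameter list.
decode_point <- function(u, space) {
  hp <- list()
  for (j in seq_along(space)) {
    p <- space[[j]]
    v <- if (isTRUE(p$log)) {
      exp(log(p$lo) + u[j] * (log(p$hi) - log(p$lo)))
    } else {
      p$lo + u[j] * (p$hi - p$lo)
    }
    if (p$type == "int") v <- as.integer(round(v))
    hp[[names(space)[j]]] <- v
  }
  hp
}

#' Bayesian optimisation over a hyperparameter space
#'
#' Sequential model-based search: a Latin-hypercube initial design followed by
#' Gaussian-process regression (squared-exponential kernel on the unit cube)
#' with expected-improvement acquisition maximised over a random candidate
#' set. Deterministic given the seed and budget. Returns the evaluated point
#' with the highest objective value.
#'
#' @param objective Function taking a named hyperparameter list, returning a
#'   scalar to maximise (e.g. mean fold AUC).
#' @param space Search space from [model_search_space()].
#' @param budget Total number of objective evaluations (>= 1).
#' @param seed Integer seed.
#' @return List with `best_hp`, `best_value` and the evaluation `history`.
#' @export
bayes_optimise <- function(objective, space, budget = 20, seed = 1) {
  if (budget < 1) stop("validation error: budget must be >= 1 evaluation")
  if (!length(space)) {
    val <- objective(list())
    return(list(best_hp = list(), best_value = val,
                history = data.frame(eval = 1, value = val)))
  }
  set.seed(seed)
  d <- length(space)
  n_init <- min(budget, max(2, min(2 * d, budget)))
  U <- lhs::maximinLHS(n_init, d)
  vals <- numeric(0)
  evals <- list()
  for (i in seq_len(n_init)) {
    evals[[i]] <- U[i, ]
    vals[i] <- objective(decode_point(U[i, ], space))
  }
  while (length(vals) < budget) {
    Xd <- do.call(rbind, evals)
    y <- vals
    ok <- is.finite(y)
    if (!any(ok)) stop("all hyperparameter evaluations failed")
    ymu <- mean(y[ok]); ysd <- stats::sd(y[ok])
    if (!is.finite(ysd) || ysd == 0) ysd <- 1
    ys <- (y - ymu) / ysd
    ys[!ok] <- min(ys[ok]) - 1
    ell <- 0.3 * sqrt(d)
    K <- exp(-as.matrix(stats::dist(Xd))^2 / (2 * ell^2)) +
      diag(1e-4, nrow(Xd))
    L <- chol(K)
    alpha <- backsolve(L, forwardsolve(t(L), ys))
    cand <- matrix(stats::runif(500 * d), ncol = d)
    Kc <- exp(-(outer(rowSums(cand^2), rep(1, nrow(Xd))) +
                  outer(rep(1, nrow(cand)), rowSums(Xd^2)) -
                  2 * cand %*% t(Xd)) / (2 * ell^2))
    mu <- as.numeric(Kc %*% alpha)
    v <- forwardsolve(t(L), t(Kc))
    s2 <- pmax(1e-12, 1 - colSums(v^2))
    s <- sqrt(s2)
    best <- max(ys[ok])
    z <- (mu - best) / s
    ei <- s * (z * stats::pnorm(z) + stats::dnorm(z))
    pick <- cand[which.max(ei), ]
    evals[[length(evals) + 1L]] <- pick
    vals[length(vals) + 1L] <- objective(decode_point(pick, space))
  }
  best_i <- which.max(vals)
  list(best_hp = decode_point(evals[[best_i]], space),
       best_value = vals[best_i],
       history = data.frame(eval = seq_along(vals), value = vals))
}

#' Tune a classifier family by cross-validated AUC
#'
#' @param family Classifier family.
#' @param records Training records (transformed features).
#' @param folds Fold ids from [make_folds()].
#' @param budget Number of configurations evaluated.
#' @param seed Integer seed.
#' @param features Feature column names.
#' @return List with `best_hp`, `best_value` (mean fold AUC), `history`.
#' @export
tune <- function(family, records, folds, budget = 20, seed = 1,
                 features = FHR_FEATURES) {
  family <- match.arg(family, MODEL_FAMILIES)
  space <- model_search_space(family)
  objective <- function(hp) {
    cv <- tryCatch(
      cross_validate(family, records, folds, hp, features, seed = seed),
      error = function(e) NULL)
    if (is.null(cv)) return(NA_real_)
    mean(cv$fold_auc)
  }
  bayes_optimise(objective, space, budget = budget, seed = seed)
}

#' Compare cross-validated models
#'
#' Ranks model families by median fold AUC, runs a Kruskal-Wallis omnibus
#' test across the per-fold AUC vectors and all pairwise two-sided
#' Mann-Whitney U tests at the 0.01 significance threshold. All models must
#' share the same fold definitions so comparisons are paired on data.
#'
#' @param cv_results Named list of results from [cross_validate()] (>= 2).
#' @return List with `ranking` (data frame), `kruskal` (htest) and
#'   `pairwise` (data frame of U statistics and p values); or `NULL` with a
#'   warning when fewer than two models are supplied.
#' @export
compare_models <- function(cv_results) {
  if (length(cv_results) < 2) {
    warning("fewer than two models: comparison skipped")
    return(NULL)
  }
  fd <- lapply(cv_results, `[[`, "folds")
  if (!all(vapply(fd, identical, logical(1), fd[[1]]))) {
    stop("validation error: fold definitions differ across models")
  }
  aucs <- lapply(cv_results, `[[`, "fold_auc")
  nm <- names(aucs)
  ranking <- data.frame(
    family = nm,
    mean_auc = vapply(aucs, mean, numeric(1)),
    median_auc = vapply(aucs, stats::median, numeric(1)),
    row.names = NULL)
  ranking <- ranking[order(ranking$median_auc, decreasing = TRUE), ]
  kw <- stats::kruskal.test(unlist(aucs),
                            factor(rep(nm, lengths(aucs))))
  cmb <- utils::combn(nm, 2)
  pw <- data.frame(model_a = cmb[1, ], model_b = cmb[2, ],
                   statistic = NA_real_, p_value = NA_real_,
                   significant = NA)
  for (i in seq_len(ncol(cmb))) {
    wt <- suppressWarnings(stats::wilcox.test(aucs[[cmb[1, i]]],
                                              aucs[[cmb[2, i]]],
                                              exact = FALSE))
    pw$statistic[i] <- unname(wt$statistic)
    pw$p_value[i] <- wt$p.value
  }
  pw$significant <- pw$p_value < 0.01
  list(ranking = ranking, kruskal = kw, pairwise = pw, alpha = 0.01)
}

#' Fit the final model on the full training set
#'
#' For probability-native families the classifier's probabilities are used
#' directly. For the margin-based SVM a monotone logistic link is fitted on
#' out-of-fold decision values so the final model emits calibrated-range
#' probabilities in [0, 1].
#'
#' @param family Classifier family.
#' @param records Full (transformed) training records.
#' @param hp Tuned hyperparameters.
#' @param seed Integer seed (same seed gives identical predictions).
#' @param features Feature column names.
#' @param calib_folds Internal folds used to calibrate margin outputs.
#' @return Object of class `fhr_model`.
#' @export
fit_final <- function(family, records, hp = list(), seed = 1,
                      features = FHR_FEATURES, calib_folds = 5) {
  family <- match.arg(family, MODEL_FAMILIES)
  X <- records[, features, drop = FALSE]
  if (any(!vapply(X, is.numeric, logical(1))) || anyNA(X) ||
      any(!is.finite(as.matrix(X)))) {
    stop("validation error: non-finite feature values in training data")
  }
  y <- as.integer(records$cohort == "APO")
  fit <- fit_classifier(family, X, y, hp, seed = seed)
  calibrator <- NULL
  if (family == "support_vector_machine") {
    set.seed(seed)
    fold <- sample(rep_len(seq_len(calib_folds), nrow(X)))
    dv <- rep(NA_real_, nrow(X))
    for (f in seq_len(calib_folds)) {
      fi <- fit_classifier(family, X[fold != f, , drop = FALSE],
                           y[fold != f], hp, seed = seed + f)
      dv[fold == f] <- score_classifier(family, fi, X[fold == f, , drop = FALSE])
    }
    calibrator <- suppressWarnings(
      stats::glm(y ~ dv, family = stats::binomial(),
                 data = data.frame(y = y, dv = dv)))
  }
  structure(list(family = family, fit = fit, hp = hp, seed = seed,
                 features = features, calibrator = calibrator),
            class = "fhr_model")
}

#' Predict adverse-outcome probabilities
#'
#' @param object An `fhr_model`.
#' @param newdata Records containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
predict.fhr_model <- function(object, newdata, ...) {
  s <- score_classifier(object$family, object$fit,
                        newdata[, object$features, drop = FALSE])
  if (!is.null(object$calibrator)) {
    s <- stats::predict(object$calibrator, data.frame(dv = s),
                        type = "response")
  }
  pmin(pmax(as.numeric(s), 0), 1)
}

#' Feature importances of a tree-ensemble model
#'
#' Mean impurity improvement attributable to each feature, averaged across
#' all trees and normalised to sum to one.
#'
#' @param model An `fhr_model` of family `random_forest` or
#'   `gradient_boosted_trees`.
#' @return Named numeric vector (sums to 1) over the model's features.
#' @export
feature_importances <- function(model) {
  stopifnot(inherits(model, "fhr_model"))
  if (model$family == "random_forest") {
    imp <- ranger::importance(model$fit)
  } else if (model$family == "gradient_boosted_trees") {
    tab <- xgboost::xgb.importance(model = model$fit)
    imp <- stats::setNames(rep(0, length(model$features)), model$features)
    imp[tab$Feature] <- tab$Gain
  } else {
    stop("unsupported-model: feature importances require a tree ensemble, got ",
         model$family)
  }
  imp <- pmax(imp, 0)
  imp / sum(imp)
}
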