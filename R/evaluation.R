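# Discrimination, calibration, operating-point, stratified and
# decision-analytic evaluation of a trained risk model.

#' @keywords internal
#' AUC by the rank (Mann-Whitney) formulation:
#' P(score_case > score_control) + 0.5 P(tie).
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("validation error: both classes must be present to compute an AUC")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC
#'
#' Computes the full ROC curve (one point per distinct score threshold, with
#' the (0,0) and (1,1) endpoints) and the AUC by the rank formulation, which
#' agrees with trapezoidal integration of the curve to numerical precision.
#'
#' @param scores Numeric risk scores (higher = more likely case).
#' @param labels 0/1 vector (1 = case).
#' @return Object of class `fhr_roc`: data frame `curve` (threshold,
#'   sensitivity, specificity, ordered by descending threshold), `auc`,
#'   `auc_trapezoid`, `n_cases`, `n_controls`.
#' @export
roc_and_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (anyNA(scores) || anyNA(labels)) {
    stop("validation error: scores and labels must be complete")
  }
  auc <- auc_rank(scores, labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  sl <- labels[ord]
  ss <- scores[ord]
  tp <- cumsum(sl)
  fp <- cumsum(1 - sl)
  last <- !duplicated(ss, fromLast = TRUE)
  sens <- tp[last] / n1
  spec <- 1 - fp[last] / n0
  curve <- data.frame(threshold = ss[last], sensitivity = sens,
                      specificity = spec)
  curve <- rbind(data.frame(threshold = Inf, sensitivity = 0, specificity = 1),
                 curve)
  fpr <- 1 - curve$specificity
  auc_trap <- sum(diff(fpr) * (utils::head(curve$sensitivity, -1) +
                                 utils::tail(curve$sensitivity, -1)) / 2)
  structure(list(curve = curve, auc = auc, auc_trapezoid = auc_trap,
                 n_cases = n1, n_controls = n0),
            class = "fhr_roc")
}

#' @export
print.fhr_roc <- function(x, ...) {
  cat(sprintf("<ROC: AUC %.4f (%d cases / %d controls, %d thresholds)>\n",
              x$auc, x$n_cases, x$n_controls, nrow(x$curve)))
  invisible(x)
}

#' Stratified bootstrap confidence interval
#'
#' Percentile interval of a metric over `B` class-stratified resamples
#' (resampling within cases and controls separately preserves prevalence, so
#' one-class resamples cannot occur). Deterministic given the seed.
#'
#' @param metric Function `(scores, labels) -> scalar`.
#' @param scores,labels Evaluation data.
#' @param B Number of bootstrap resamples (>= 100).
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return Named vector `c(lo=, hi=)`.
#' @export
bootstrap_ci <- function(metric, scores, labels, B = 1000, level = 0.95,
                         seed = 1) {
  if (B < 100) stop("validation error: B must be >= 100")
  labels <- as.integer(labels)
  set.seed(seed)
  i1 <- which(labels == 1)
  i0 <- which(labels == 0)
  stat <- vapply(seq_len(B), function(b) {
    idx <- c(sample_safe(i1, replace = TRUE),
             sample_safe(i0, replace = TRUE))
    metric(scores[idx], labels[idx])
  }, numeric(1))
  a <- (1 - level) / 2
  q <- stats::quantile(stat, c(a, 1 - a), names = FALSE, na.rm = TRUE)
  c(lo = q[1], hi = q[2])
}

#' @keywords internal
#' Confusion-matrix metrics at a threshold (classify positive when
#' score >= threshold). Returns proportions in [0, 1].
confusion_metrics <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0) {
    2 * prec * sens / (prec + sens)
  } else 0
  n <- tp + fp + tn + fn
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 0
  c(sensitivity = sens, specificity = spec, f1 = f1, kappa = kappa,
    tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Operating points: Youden, 95% sensitivity, 95% specificity
#'
#' Selects three probability thresholds on the ROC curve: the Youden index
#' (sensitivity + specificity - 1 maximised; ties broken toward the lower
#' threshold, i.e. higher sensitivity), the highest threshold retaining at
#' least 95% sensitivity, and the lowest threshold achieving at least 95%
#' specificity. Sensitivity, specificity, F1 and Cohen's kappa are reported
#' on the x100 percentage scale with stratified bootstrap CIs. Unattainable
#' constraints are reported as such, never silently clamped.
#'
#' @param scores Probabilities in [0, 1].
#' @param labels 0/1 outcome vector.
#' @param level CI level.
#' @param B Bootstrap resamples.
#' @param seed Integer seed.
#' @return Data frame with one row per operating point: `name`,
#'   `threshold_pct`, `attainable`, and `sensitivity`, `specificity`, `f1`,
#'   `kappa` (each x100 with `_lo`/`_hi` CI columns).
#' @export
operating_points <- function(scores, labels, level = 0.95, B = 1000, seed = 1) {
  roc <- roc_and_auc(scores, labels)
  cv <- roc$curve[is.finite(roc$curve$threshold), , drop = FALSE]
  youden <- cv$sensitivity + cv$specificity - 1
  i_y <- which(youden == max(youden))
  thr_y <- min(cv$threshold[i_y])  # lowest threshold on ties
  ok_sens <- cv$sensitivity >= 0.95
  thr_s <- if (any(ok_sens)) max(cv$threshold[ok_sens]) else NA_real_
  ok_spec <- cv$specificity >= 0.95
  thr_p <- if (any(ok_spec)) min(cv$threshold[ok_spec]) else NA_real_
  pts <- data.frame(name = c("youden", "sens95", "spec95"),
                    threshold = c(thr_y, thr_s, thr_p))
  rows <- lapply(seq_len(nrow(pts)), function(i) {
    thr <- pts$threshold[i]
    if (is.na(thr)) {
      return(data.frame(name = pts$name[i], threshold_pct = NA_real_,
                        attainable = FALSE,
                        sensitivity = NA_real_, sensitivity_lo = NA_real_,
                        sensitivity_hi = NA_real_,
                        specificity = NA_real_, specificity_lo = NA_real_,
                        specificity_hi = NA_real_,
                        f1 = NA_real_, f1_lo = NA_real_, f1_hi = NA_real_,
                        kappa = NA_real_, kappa_lo = NA_real_,
                        kappa_hi = NA_real_))
    }
    cm <- confusion_metrics(scores, labels, thr)
    cis <- lapply(c("sensitivity", "specificity", "f1", "kappa"), function(mt) {
      bootstrap_ci(function(s, l) confusion_metrics(s, l, thr)[[mt]],
                   scores, labels, B = B, level = level, seed = seed)
    })
    names(cis) <- c("sensitivity", "specificity", "f1", "kappa")
    data.frame(name = pts$name[i], threshold_pct = 100 * thr,
               attainable = TRUE,
               sensitivity = 100 * cm[["sensitivity"]],
               sensitivity_lo = 100 * cis$sensitivity[["lo"]],
               sensitivity_hi = 100 * cis$sensitivity[["hi"]],
               specificity = 100 * cm[["specificity"]],
               specificity_lo = 100 * cis$specificity[["lo"]],
               specificity_hi = 100 * cis$specificity[["hi"]],
               f1 = 100 * cm[["f1"]],
               f1_lo = 100 * cis$f1[["lo"]], f1_hi = 100 * cis$f1[["hi"]],
               kappa = 100 * cm[["kappa"]],
               kappa_lo = 100 * cis$kappa[["lo"]],
               kappa_hi = 100 * cis$kappa[["hi"]])
  })
  do.call(rbind, rows)
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes; lower is better calibrated.
#'
#' @param probabilities Probabilities in [0, 1].
#' @param labels 0/1 outcome vector.
#' @return Brier score in [0, 1].
#' @export
brier <- function(probabilities, labels) {
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE) ||
      anyNA(probabilities)) {
    stop("validation error: probabilities must lie in [0, 1]")
  }
  mean((probabilities - as.integer(labels))^2)
}

#' Decision-curve analysis
#'
#' Net benefit of the model, NB(pt) = TP/N - (FP/N) * pt/(1-pt) classifying
#' positive at probability threshold pt, compared against treat-all
#' (NB = prevalence - (1-prevalence) * pt/(1-pt)) and treat-none (NB = 0)
#' across thresholds 0.01 to 0.99.
#'
#' @param probabilities Probabilities in [0, 1].
#' @param labels 0/1 outcome vector.
#' @param grid Threshold grid (1 is excluded by construction).
#' @return Object of class `fhr_decision_curve`: data frame `curve`
#'   (threshold, nb_model, nb_treat_all, nb_treat_none), `prevalence`, and
#'   the threshold ranges where the model dominates each baseline.
#' @export
decision_curve <- function(probabilities, labels,
                           grid = seq(0.01, 0.99, by = 0.01)) {
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE)) {
    stop("validation error: probabilities must lie in [0, 1]")
  }
  grid <- grid[grid < 1 & grid > 0]
  labels <- as.integer(labels)
  n <- length(labels)
  prev <- mean(labels)
  nb <- vapply(grid, function(pt) {
    pred <- probabilities >= pt
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    tp / n - (fp / n) * pt / (1 - pt)
  }, numeric(1))
  nb_all <- prev - (1 - prev) * grid / (1 - grid)
  curve <- data.frame(threshold = grid, nb_model = nb, nb_treat_all = nb_all,
                      nb_treat_none = 0)
  beats_all <- grid[nb > nb_all]
  beats_none <- grid[nb > 0]
  structure(list(curve = curve, prevalence = prev,
                 dominates_treat_all = range_or_na(beats_all),
                 dominates_treat_none = range_or_na(beats_none)),
            class = "fhr_decision_curve")
}

#' @keywords internal
range_or_na <- function(x) if (length(x)) range(x) else c(NA_real_, NA_real_)

#' @export
print.fhr_decision_curve <- function(x, ...) {
  cat(sprintf("<decision curve: prevalence %.3f; model > treat-all on [%.2f, %.2f]>\n",
              x$prevalence, x$dominates_treat_all[1], x$dominates_treat_all[2]))
  invisible(x)
}

#' Stratified AUC
#'
#' Per-stratum ROC/AUC with bootstrap CIs. For gestational-week strata the
#' records are partitioned; for adverse-outcome subtypes each stratum
#' compares that subtype's cases against all controls (subtypes co-occur, so
#' a one-vs-all-controls framing is used). Strata below `min_cases` cases are
#' flagged, not dropped; strata with one class yield an `NA` AUC, reported as
#' undefined.
#'
#' @param scores Risk scores.
#' @param labels 0/1 outcome vector.
#' @param strata Either a vector of stratum ids (partition) or a 0/1 matrix /
#'   data frame of subtype indicators (one-vs-all-controls).
#' @param min_cases Minimum cases for an unflagged stratum.
#' @param B,level,seed Bootstrap parameters.
#' @return List with `per_stratum` (data frame: stratum, n_cases, n_controls,
#'   auc, lo, hi, flagged, defined) and `summary` (median and IQR of defined
#'   AUCs).
#' @export
stratified_auc <- function(scores, labels, strata, min_cases = 5,
                           B = 500, level = 0.95, seed = 1) {
  labels <- as.integer(labels)
  one_vs_controls <- is.matrix(strata) || is.data.frame(strata)
  eval_stratum <- function(sc, lb, name) {
    n1 <- sum(lb == 1); n0 <- sum(lb == 0)
    if (n1 == 0 || n0 == 0) {
      return(data.frame(stratum = name, n_cases = n1, n_controls = n0,
                        auc = NA_real_, lo = NA_real_, hi = NA_real_,
                        flagged = TRUE, defined = FALSE))
    }
    a <- auc_rank(sc, lb)
    ci <- bootstrap_ci(function(s, l) auc_rank(s, l), sc, lb, B = B,
                       level = level, seed = seed)
    data.frame(stratum = name, n_cases = n1, n_controls = n0, auc = a,
               lo = ci[["lo"]], hi = ci[["hi"]],
               flagged = n1 < min_cases, defined = TRUE)
  }
  rows <- if (one_vs_controls) {
    strata <- as.data.frame(strata)
    lapply(names(strata), function(nm) {
      sel <- labels == 0 | (labels == 1 & strata[[nm]] == 1)
      eval_stratum(scores[sel], labels[sel], nm)
    })
  } else {
    lapply(sort(unique(strata)), function(s) {
      sel <- strata == s
      eval_stratum(scores[sel], labels[sel], as.character(s))
    })
  }
  per <- do.call(rbind, rows)
  ok <- per$auc[per$defined]
  summary <- c(median = stats::median(ok),
               q1 = unname(stats::quantile(ok, 0.25)),
               q3 = unname(stats::quantile(ok, 0.75)))
  list(per_stratum = per, summary = summary)
}

#' Per-feature association tests and effect sizes
#'
#' Two-sided Mann-Whitney U test of each feature against the outcome at the
#' 0.05 level. Effect size is Cohen's D for approximately symmetric features
#' (|skewness| at or below `skew_threshold`, the same rule used for the
#' transforms) and the rank-biserial correlation r = 2*AUC - 1 otherwise.
#' Constant features yield p = 1 with a warning.
#'
#' @param records Records with feature columns and `cohort`.
#' @param features Feature column names.
#' @param skew_threshold Symmetry rule threshold.
#' @return Data frame: feature, p_value, significant (p < 0.05), effect_size,
#'   effect_type, direction (`"APO higher"` / `"NPO higher"`).
#' @export
feature_association_tests <- function(records, features = FHR_FEATURES,
                                      skew_threshold = 1) {
  y <- as.integer(records$cohort == "APO")
  if (sum(y) < 2 || sum(1 - y) < 2) {
    stop("validation error: need at least 2 observations per group")
  }
  rows <- lapply(features, function(cc) {
    v <- records[[cc]]
    if (length(unique(v)) == 1) {
      warning("constant feature '", cc, "': p set to 1")
      return(data.frame(feature = cc, p_value = 1, significant = FALSE,
                        effect_size = 0, effect_type = "rank_biserial",
                        direction = "none"))
    }
    wt <- suppressWarnings(stats::wilcox.test(v[y == 1], v[y == 0],
                                              exact = FALSE))
    sk <- e1071::skewness(v, type = 2)
    a <- auc_rank(v, y)
    if (is.finite(sk) && abs(sk) <= skew_threshold) {
      s_pool <- sqrt((stats::var(v[y == 1]) + stats::var(v[y == 0])) / 2)
      es <- (mean(v[y == 1]) - mean(v[y == 0])) / s_pool
      et <- "cohens_d"
    } else {
      es <- 2 * a - 1
      et <- "rank_biserial"
    }
    data.frame(feature = cc, p_value = wt$p.value,
               significant = wt$p.value < 0.05,
               effect_size = es, effect_type = et,
               direction = if (a > 0.5) "APO higher" else if (a < 0.5) "NPO higher" else "none")
  })
  do.call(rbind, rows)
}

#' Evaluate a trained model on a validation set
#'
#' Bundles discrimination (ROC/AUC with bootstrap CI), calibration (Brier),
#' the three operating points, the decision curve and stratified AUCs by
#' gestational week and adverse-outcome subtype into one report.
#'
#' @param model An `fhr_model` from [fit_final()].
#' @param validation Transformed validation records.
#' @param B Bootstrap resamples.
#' @param seed Integer seed.
#' @return List of class `fhr_evaluation`.
#' @export
evaluate_model <- function(model, validation, B = 1000, seed = 1) {
  p <- predict(model, validation)
  y <- as.integer(validation$cohort == "APO")
  roc <- roc_and_auc(p, y)
  auc_ci <- bootstrap_ci(function(s, l) auc_rank(s, l), p, y, B = B,
                         seed = seed)
  ops <- operating_points(p, y, B = B, seed = seed)
  dc <- decision_curve(p, y)
  week <- validation$gestational_age_days %/% 7
  by_week <- stratified_auc(p, y, week, B = min(B, 500), seed = seed)
  sub_cols <- grep("^subtype_", names(validation), value = TRUE)
  by_subtype <- if (length(sub_cols)) {
    stratified_auc(p, y, validation[, sub_cols, drop = FALSE],
                   B = min(B, 500), seed = seed)
  } else NULL
  structure(list(probabilities = p, labels = y, roc = roc,
                 auc = roc$auc, auc_ci = auc_ci,
                 brier = brier(p, y), operating_points = ops,
                 decision_curve = dc, auc_by_week = by_week,
                 auc_by_subtype = by_subtype, seed = seed),
            class = "fhr_evaluation")
}

#' @export
print.fhr_evaluation <- function(x, ...) {
  cat(sprintf("<evaluation: AUC %.3f (%.3f-%.3f), Brier %.3f, n=%d>\n",
              x$auc, x$auc_ci[["lo"]], x$auc_ci[["hi"]], x$brier,
              length(x$labels)))
  invisible(x)
}
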