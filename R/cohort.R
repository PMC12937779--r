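# Propensity-score matching, balanced train/validation split and feature
# transformation with training-derived parameters.

#' Estimate propensity scores
#'
#' Fits an additive logistic model of cohort membership (APO vs NPO) on
#' gestational age, fetal sex and trace duration and returns the fitted
#' probabilities. Zero-variance covariates are dropped with a warning.
#'
#' @param records Cohort records with a `cohort` column.
#' @param covariates Covariate column names.
#' @return Numeric vector of scores in (0, 1), aligned with `records`.
#' @export
estimate_propensity <- function(records,
                                covariates = c("gestational_age_days",
                                               "fetal_sex", "duration_min")) {
  missing_cols <- setdiff(covariates, names(records))
  if (length(missing_cols)) {
    stop("validation error: missing covariate column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  X <- records[, covariates, drop = FALSE]
  if (anyNA(X)) stop("validation error: covariates must be complete")
  keep <- vapply(covariates, function(cc) {
    v <- X[[cc]]
    ok <- length(unique(v)) > 1
    if (!ok) warning("dropping zero-variance covariate: ", cc)
    ok
  }, logical(1))
  covariates <- covariates[keep]
  y <- as.integer(records$cohort == "APO")
  if (!length(covariates)) return(rep(mean(y), nrow(records)))
  fml <- stats::as.formula(paste("y ~", paste(covariates, collapse = " + ")))
  dat <- cbind(data.frame(y = y), X[, covariates, drop = FALSE])
  fit <- suppressWarnings(stats::glm(fml, data = dat, family = stats::binomial()))
  p <- stats::predict(fit, type = "response")
  pmin(pmax(as.numeric(p), 1e-12), 1 - 1e-12)
}

#' @keywords internal
#' Standardized mean difference of one covariate between cohorts.
smd <- function(x, case) {
  if (is.character(x) || is.factor(x)) x <- as.numeric(factor(x))
  m1 <- mean(x[case]); m0 <- mean(x[!case])
  s <- sqrt((stats::var(x[case]) + stats::var(x[!case])) / 2)
  if (!is.finite(s) || s == 0) return(0)
  (m1 - m0) / s
}

#' Match cases to controls without replacement
#'
#' Greedy nearest-neighbour matching on the propensity score: APO cases are
#' processed in descending propensity order and each is paired with the
#' closest unused NPO control within the caliper. Controls are sampled
#' without replacement; cases with no in-caliper control remain unmatched
#' and are reported.
#'
#' @param records Cohort records.
#' @param scores Propensity scores from [estimate_propensity()].
#' @param caliper Maximum |logit score| distance; default 0.2 standard
#'   deviations of the logit score.
#' @param covariates Covariates used for the balance diagnostics.
#' @return List with `records` (matched records only), `pairs` (APO trace_id,
#'   NPO trace_id or `NA` when unmatched) and `balance` (pre/post
#'   standardized mean differences per covariate).
#' @export
match_without_replacement <- function(records, scores, caliper = NULL,
                                      covariates = c("gestational_age_days",
                                                     "fetal_sex", "duration_min")) {
  stopifnot(length(scores) == nrow(records))
  case <- records$cohort == "APO"
  if (!any(!case)) {
    warning("no NPO records: empty matching")
    return(list(records = records[0, , drop = FALSE],
                pairs = data.frame(apo = records$trace_id[case],
                                   npo = NA_character_),
                balance = NULL))
  }
  lg <- stats::qlogis(scores)
  if (is.null(caliper)) caliper <- 0.2 * stats::sd(lg)
  if (!is.finite(caliper) || caliper <= 0) caliper <- Inf
  apo_idx <- which(case)[order(scores[case], decreasing = TRUE)]
  npo_idx <- which(!case)
  npo_lg <- lg[npo_idx]
  used <- logical(length(npo_idx))
  pair_npo <- rep(NA_integer_, length(apo_idx))
  for (k in seq_along(apo_idx)) {
    d <- abs(npo_lg - lg[apo_idx[k]])
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= caliper) {
      pair_npo[k] <- npo_idx[j]
      used[j] <- TRUE
    }
  }
  pre <- vapply(covariates, function(cc) smd(records[[cc]], case), numeric(1))
  matched_idx <- c(apo_idx[!is.na(pair_npo)], pair_npo[!is.na(pair_npo)])
  out <- records[sort(matched_idx), , drop = FALSE]
  post <- vapply(covariates, function(cc) {
    smd(out[[cc]], out$cohort == "APO")
  }, numeric(1))
  n_unmatched <- sum(is.na(pair_npo))
  if (n_unmatched) {
    message(n_unmatched, " APO case(s) had no NPO control within the caliper")
  }
  list(records = out,
       pairs = data.frame(apo = records$trace_id[apo_idx],
                          npo = ifelse(is.na(pair_npo), NA_character_,
                                       records$trace_id[pair_npo]),
                          stringsAsFactors = FALSE),
       balance = data.frame(covariate = covariates, smd_pre = pre,
                            smd_post = post, row.names = NULL))
}

#' @keywords internal
#' Stratification key: outcome x completed gestational week x 10-min duration
#' bin x fetal sex.
stratum_key <- function(records) {
  paste(records$cohort,
        records$gestational_age_days %/% 7,
        pmin(records$duration_min %/% 10, 8),
        records$fetal_sex,
        sep = ":")
}

#' @keywords internal
#' Largest-remainder allocation of round(frac * N) training slots to strata.
largest_remainder <- function(n_per_stratum, frac) {
  total <- round(frac * sum(n_per_stratum))
  base <- floor(frac * n_per_stratum)
  rem <- frac * n_per_stratum - base
  extra <- total - sum(base)
  if (extra > 0) {
    ord <- order(rem, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  } else if (extra < 0) {
    ord <- order(rem)
    take <- ord[base[ord] > 0][seq_len(-extra)]
    base[take] <- base[take] - 1
  }
  base
}

#' Stratified train/validation split
#'
#' Randomly splits records into training and validation parts, balanced for
#' outcome, gestational age (completed weeks), trace duration (10-minute
#' bins) and fetal sex. Per-stratum training counts use largest-remainder
#' rounding so the global training size is exactly `round(fraction * N)`.
#' Singleton strata go to training with a warning.
#'
#' @param records Cohort records.
#' @param fraction Training fraction (default 0.8).
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return List with `train`, `validation` (disjoint, exhaustive), `fraction`
#'   and `seed`.
#' @export
stratified_split <- function(records, fraction = 0.8, seed = 1) {
  if (!nrow(records)) stop("validation error: no records to split")
  set.seed(seed)
  key <- stratum_key(records)
  strata <- split(seq_len(nrow(records)), key)
  sizes <- lengths(strata)
  if (any(sizes == 1)) {
    warning(sum(sizes == 1), " singleton stratum(/a) assigned to training")
  }
  n_train <- largest_remainder(sizes, fraction)
  train_idx <- integer(0)
  for (s in seq_along(strata)) {
    idx <- strata[[s]]
    k <- n_train[s]
    if (length(idx) == 1) {
      if (k >= 1) train_idx <- c(train_idx, idx)
      else train_idx <- c(train_idx, idx)  # singleton: force to training
    } else {
      train_idx <- c(train_idx, sample_safe(idx, k))
    }
  }
  # singletons forced into training may overshoot; rebalance from the largest
  # strata to keep the global 80:20 arithmetic exact
  overshoot <- length(train_idx) - round(fraction * nrow(records))
  if (overshoot > 0) {
    movable <- train_idx[!train_idx %in% unlist(strata[sizes == 1])]
    drop <- sample_safe(movable, overshoot)
    train_idx <- setdiff(train_idx, drop)
  }
  train_idx <- sort(train_idx)
  list(train = records[train_idx, , drop = FALSE],
       validation = records[-train_idx, , drop = FALSE],
       fraction = fraction, seed = seed)
}

#' Fit per-feature transformation parameters on training data
#'
#' Features with approximately symmetric distributions (|sample skewness| at
#' most `skew_threshold`) are standardised by z-score; skewed features are
#' min-max rescaled to [0, 1] on the training range. Parameters are fitted on
#' training data only and applied unchanged elsewhere.
#'
#' @param train Training records containing the feature columns.
#' @param features Feature column names (default: the seven FHR features).
#' @param skew_threshold Absolute skewness above which min-max is used.
#' @return Object of class `fhr_transforms`.
#' @export
fit_transforms <- function(train,
                           features = c("basal_fhr", "accelerations",
                                        "decelerations", "most_lost_beats",
                                        "stv", "high_variation_min",
                                        "low_variation_min"),
                           skew_threshold = 1) {
  params <- lapply(features, function(cc) {
    v <- train[[cc]]
    if (is.null(v)) stop("validation error: missing feature column ", cc)
    if (anyNA(v)) stop("validation error: feature ", cc, " has missing values")
    if (length(unique(v)) == 1) {
      stop("degenerate feature '", cc, "': constant in training data")
    }
    sk <- e1071::skewness(v, type = 2)
    if (is.finite(sk) && abs(sk) > skew_threshold) {
      list(rule = "minmax", min = min(v), max = max(v), skewness = sk)
    } else {
      list(rule = "zscore", mean = mean(v), sd = stats::sd(v), skewness = sk)
    }
  })
  names(params) <- features
  structure(list(params = params, features = features,
                 skew_threshold = skew_threshold),
            class = "fhr_transforms")
}

#' Apply fitted transformations
#'
#' Applies [fit_transforms()] parameters without re-estimation. Min-max
#' outputs outside [0, 1] (possible on validation data) are reported via a
#' message, never clipped.
#'
#' @param transforms An `fhr_transforms` object.
#' @param records Records containing the feature columns.
#' @return `records` with transformed feature columns.
#' @export
apply_transforms <- function(transforms, records) {
  stopifnot(inherits(transforms, "fhr_transforms"))
  out <- records
  for (cc in transforms$features) {
    p <- transforms$params[[cc]]
    v <- records[[cc]]
    if (p$rule == "zscore") {
      out[[cc]] <- (v - p$mean) / p$sd
    } else {
      out[[cc]] <- (v - p$min) / (p$max - p$min)
      n_out <- sum(out[[cc]] < 0 | out[[cc]] > 1)
      if (n_out) {
        message(n_out, " value(s) of ", cc,
                " fall outside [0,1] under training min-max (not clipped)")
      }
    }
  }
  out
}
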