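# Propensity estimation, matching without replacement, stratified splitting
# and training-derived feature transforms.

test_that("propensity scores are probabilities and equal for identical records", {
  rec <- toy_records(n_per = 50, seed = 3)
  p <- estimate_propensity(rec)
  expect_true(all(p > 0 & p < 1))
  twin <- rec[c(1, 1), ]
  twin$cohort <- c("NPO", "APO")
  p2 <- estimate_propensity(rbind(rec, twin))
  expect_equal(p2[nrow(rec) + 1], p2[nrow(rec) + 2])
})

test_that("zero-variance covariates are dropped with a warning", {
  rec <- toy_records(n_per = 30, seed = 4)
  rec$duration_min <- 45
  expect_warning(p <- estimate_propensity(rec), "zero-variance")
  expect_true(all(p > 0 & p < 1))
})

test_that("matching is greedy nearest-neighbour without replacement", {
  rec <- data.frame(trace_id = c("a1", "n1", "n2"),
                    cohort = c("APO", "NPO", "NPO"),
                    gestational_age_days = c(200, 201, 220),
                    fetal_sex = "male", duration_min = c(40, 41, 55),
                    stringsAsFactors = FALSE)
  m <- match_without_replacement(rec, c(0.5, 0.49, 0.60), caliper = Inf)
  expect_equal(m$pairs$npo[m$pairs$apo == "a1"], "n1")

  rec2 <- data.frame(trace_id = c("a1", "a2", "n1"),
                     cohort = c("APO", "APO", "NPO"),
                     gestational_age_days = c(200, 205, 201),
                     fetal_sex = "male", duration_min = c(40, 42, 41),
                     stringsAsFactors = FALSE)
  m2 <- suppressMessages(
    match_without_replacement(rec2, c(0.5, 0.52, 0.51), caliper = Inf))
  expect_equal(sum(!is.na(m2$pairs$npo)), 1)   # one pair only
  expect_equal(sum(is.na(m2$pairs$npo)), 1)    # one unmatched APO
  expect_equal(nrow(m2$records), 2)
})

test_that("matching improves covariate balance on a shifted cohort", {
  set.seed(7)
  n <- 200
  cohort <- rep(c("NPO", "APO"), each = n / 2)
  rec <- data.frame(
    trace_id = sprintf("t%03d", 1:n),
    cohort = cohort,
    gestational_age_days = round(ifelse(cohort == "APO",
                                        rnorm(n, 235, 12), rnorm(n, 215, 12))),
    fetal_sex = sample(c("male", "female"), n, TRUE),
    duration_min = ifelse(cohort == "APO", rnorm(n, 55, 8), rnorm(n, 48, 8)),
    stringsAsFactors = FALSE)
  rec$gestational_age_days <- pmin(pmax(rec$gestational_age_days, 189), 258)
  p <- estimate_propensity(rec)
  m <- suppressMessages(match_without_replacement(rec, p))
  # brute-force SMD check: post-match |SMD| < pre-match |SMD| for the shifted
  # covariates
  for (cc in c("gestational_age_days", "duration_min")) {
    expect_lt(abs(m$balance$smd_post[m$balance$covariate == cc]),
              abs(m$balance$smd_pre[m$balance$covariate == cc]))
  }
  # without replacement: no control appears twice
  used <- m$pairs$npo[!is.na(m$pairs$npo)]
  expect_equal(anyDuplicated(used), 0)
})

test_that("stratified split is a deterministic partition with exact sizes", {
  rec <- toy_records(n_per = 50, seed = 5)
  sp <- suppressWarnings(stratified_split(rec, seed = 42))
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$validation), 20)
  expect_setequal(c(sp$train$trace_id, sp$validation$trace_id), rec$trace_id)
  sp2 <- suppressWarnings(stratified_split(rec, seed = 42))
  expect_identical(sp$train$trace_id, sp2$train$trace_id)

  # N = 10, one stratum -> 8/2
  one <- rec[1:10, ]
  one$cohort <- "NPO"; one$fetal_sex <- "male"
  one$gestational_age_days <- 210; one$duration_min <- 45
  sp3 <- stratified_split(one, seed = 1)
  expect_equal(nrow(sp3$train), 8)
  expect_equal(nrow(sp3$validation), 2)
})

test_that("per-stratum class balance holds within one record", {
  rec <- toy_records(n_per = 120, seed = 6)
  # populated strata: four gestational weeks, one duration bin
  rec$gestational_age_days <- sample(c(200, 210, 220, 230), 240, replace = TRUE)
  rec$duration_min <- 45
  sp <- stratified_split(rec, seed = 9)
  key <- paste(sp$train$cohort, sp$train$gestational_age_days %/% 7,
               sp$train$fetal_sex)
  key_all <- paste(rec$cohort, rec$gestational_age_days %/% 7, rec$fetal_sex)
  # every stratum contributes floor/ceiling of 80% of its size to training
  for (k in unique(key_all)) {
    n_k <- sum(key_all == k)
    expect_lte(abs(sum(key == k) - 0.8 * n_k), 1)
  }
  p_train <- mean(sp$train$cohort == "APO")
  expect_lt(abs(p_train - 0.5), 0.02)
})

test_that("transforms are fitted on training data only and never re-estimated", {
  rec <- toy_records(n_per = 100, seed = 8)
  # force a skewed feature so both rules are exercised
  rec$most_lost_beats <- rlnorm(200, log(10), 0.9)
  tf <- fit_transforms(rec)
  rules <- vapply(tf$params, `[[`, character(1), "rule")
  expect_true("minmax" %in% rules && "zscore" %in% rules)
  expect_equal(unname(rules["most_lost_beats"]), "minmax")

  tr_t <- apply_transforms(tf, rec)
  for (cc in names(rules)[rules == "zscore"]) {
    expect_equal(mean(tr_t[[cc]]), 0, tolerance = 1e-12)
    expect_equal(sd(tr_t[[cc]]), 1, tolerance = 1e-12)
  }
  for (cc in names(rules)[rules == "minmax"]) {
    expect_equal(range(tr_t[[cc]]), c(0, 1), tolerance = 1e-12)
  }

  # a validation value above the training max exceeds 1, logged, not clipped
  valid <- rec[1, ]
  valid$most_lost_beats <- max(rec$most_lost_beats) * 2
  expect_message(va_t <- apply_transforms(tf, valid), "outside")
  expect_gt(va_t$most_lost_beats, 1)

  # idempotence: refitting on transformed training data gives identity params
  tf2 <- fit_transforms(tr_t)
  for (cc in names(rules)[rules == "zscore"]) {
    if (tf2$params[[cc]]$rule == "zscore") {
      expect_equal(tf2$params[[cc]]$mean, 0, tolerance = 1e-10)
      expect_equal(tf2$params[[cc]]$sd, 1, tolerance = 1e-10)
    }
  }

  rec$stv <- 5
  expect_error(fit_transforms(rec), "degenerate feature 'stv'")
})
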