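# Discrimination, calibration, operating points, decision curves, stratified
# AUCs and feature association tests.

test_that("AUC matches exhaustive pair counting and trapezoid integration", {
  # brute force over all 4 case-control pairs
  expect_equal(auc_on(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0)), 1.0)

  set.seed(1)
  s <- round(runif(300), 2)  # ties on purpose
  y <- rbinom(300, 1, 0.4)
  pairs <- outer(s[y == 1], s[y == 0], function(a, b) {
    (a > b) + 0.5 * (a == b)
  })
  roc <- roc_and_auc(s, y)
  expect_equal(roc$auc, mean(pairs), tolerance = 1e-12)
  expect_equal(roc$auc, roc$auc_trapezoid, tolerance = 1e-12)
  # endpoints present
  expect_equal(roc$curve$sensitivity[1], 0)
  expect_equal(roc$curve$specificity[1], 1)
  expect_equal(roc$curve$sensitivity[nrow(roc$curve)], 1)
  expect_equal(roc$curve$specificity[nrow(roc$curve)], 0)
  # sensitivity non-decreasing as the threshold falls
  expect_true(all(diff(roc$curve$sensitivity) >= 0))

  expect_error(roc_and_auc(s, rep(1, 300)), "both classes")
})

test_that("AUC agrees with an independent implementation (pROC)", {
  skip_if_not_installed("pROC")
  set.seed(2)
  s <- rnorm(400)
  y <- rbinom(400, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(auc_on(s, y), ref, tolerance = 1e-10)
})

test_that("labels independent of scores give chance-level AUC", {
  set.seed(3)
  s <- runif(10000)
  y <- rbinom(10000, 1, 0.5)
  expect_lt(abs(auc_on(s, y) - 0.5), 0.02)
})

test_that("bootstrap CIs are deterministic, centred and degenerate when constant", {
  set.seed(4)
  s <- c(runif(60, 0.5, 1), runif(60, 0, 0.5))
  y <- rep(c(1, 0), each = 60)
  ci <- bootstrap_ci(function(sc, l) auc_on(sc, l), s, y, B = 300, seed = 5)
  expect_identical(ci, bootstrap_ci(function(sc, l) auc_on(sc, l), s, y,
                                    B = 300, seed = 5))
  a <- auc_on(s, y)
  expect_lte(ci[["lo"]], a)
  expect_gte(ci[["hi"]], a)

  const <- bootstrap_ci(function(sc, l) 0.42, s, y, B = 200, seed = 1)
  expect_equal(unname(const), c(0.42, 0.42))
  expect_error(bootstrap_ci(function(sc, l) 0, s, y, B = 50), "B must be")
})

test_that("operating-point metrics match the closed-form confusion matrix", {
  # TP=40, FN=10, TN=40, FP=10 at threshold 0.5
  y <- c(rep(1, 50), rep(0, 50))
  s <- c(rep(0.9, 40), rep(0.1, 10), rep(0.1, 40), rep(0.9, 10))
  cm <- fhrrisk:::confusion_metrics(s, y, 0.5)
  expect_equal(unname(cm["sensitivity"]), 0.8)
  expect_equal(unname(cm["specificity"]), 0.8)
  expect_equal(unname(cm["kappa"]), 0.6, tolerance = 1e-12)

  # perfect classifier: Youden point is perfect, kappa 1
  yp <- rep(c(1, 0), each = 30)
  sp <- c(runif(30, 0.8, 1), runif(30, 0, 0.2))
  ops <- operating_points(sp, yp, B = 200, seed = 1)
  youden <- ops[ops$name == "youden", ]
  expect_equal(youden$sensitivity, 100)
  expect_equal(youden$specificity, 100)
  expect_equal(youden$kappa, 100)
  expect_true(all(ops$attainable))
})

test_that("kappa is near zero at the Youden point for uninformative scores", {
  set.seed(6)
  y <- rbinom(2000, 1, 0.5)
  s <- runif(2000)
  ops <- operating_points(s, y, B = 100, seed = 2)
  expect_lt(abs(ops$kappa[ops$name == "youden"]), 10)  # x100 scale
})

test_that("unattainable operating constraints are reported, not clamped", {
  # all cases score below all controls: no threshold reaches 95% sensitivity
  # with any specificity — but sens95 picks the lowest score; build ties so
  # sensitivity can only be 0 or 1 at extremes and check the spec95 side
  y <- c(rep(1, 5), rep(0, 5))
  s <- rep(0.5, 10)  # a single threshold: sens 100%, spec 0%
  ops <- operating_points(s, y, B = 100, seed = 1)
  expect_false(ops$attainable[ops$name == "spec95"])
  expect_true(is.na(ops$threshold_pct[ops$name == "spec95"]))
})

test_that("brier score matches its closed forms", {
  y <- c(1, 1, 0, 0)
  expect_equal(brier(c(1, 1, 0, 0), y), 0)
  expect_equal(brier(rep(0.5, 4), y), 0.25)
  # constant p on prevalence pi: pi (1-p)^2 + (1-pi) p^2
  y2 <- rep(c(1, 0), each = 500)
  expect_equal(brier(rep(0.3, 1000), y2), 0.5 * 0.49 + 0.5 * 0.09)
  expect_equal(brier(rep(0.3, 1000), y2), 0.29, tolerance = 1e-12)
  expect_error(brier(c(0.5, 1.2), c(0, 1)), "probabilities")
})

test_that("decision-curve identities hold", {
  # hand-computable case: N=100, TP=30, FP=10 at pt=0.2 -> NB = 0.275
  y <- c(rep(1, 40), rep(0, 60))
  p <- c(rep(0.9, 30), rep(0.1, 10),   # 30 TP, 10 FN at 0.2
         rep(0.9, 10), rep(0.1, 50))   # 10 FP, 50 TN
  dc <- decision_curve(p, y)
  row <- dc$curve[abs(dc$curve$threshold - 0.2) < 1e-9, ]
  expect_equal(row$nb_model, 0.3 - 0.1 * 0.25, tolerance = 1e-12)
  expect_true(all(dc$curve$nb_treat_none == 0))
  # treat-all crosses zero exactly at pt = prevalence
  expect_equal(dc$prevalence - (1 - dc$prevalence) *
                 dc$prevalence / (1 - dc$prevalence), 0)
  i <- which.min(abs(dc$curve$threshold - dc$prevalence))
  expect_lt(abs(dc$curve$nb_treat_all[i]), 0.011)
  # model never beats the perfect classifier (NB = prevalence)
  expect_true(all(dc$curve$nb_model <= dc$prevalence + 1e-12))

  # perfect classifier: NB = prevalence for thresholds below min case prob
  yp <- rep(c(1, 0), each = 50)
  pp <- c(runif(50, 0.7, 1), runif(50, 0, 0.3))
  dcp <- decision_curve(pp, yp)
  low <- dcp$curve$threshold < 0.7 & dcp$curve$threshold > 0.3
  expect_true(all(abs(dcp$curve$nb_model[low] - 0.5) < 1e-12))
})

test_that("stratified AUC handles whole-set, one-class and subtype strata", {
  set.seed(8)
  y <- rbinom(300, 1, 0.5)
  s <- runif(300) + 0.5 * y
  whole <- stratified_auc(s, y, rep("all", 300), B = 100, seed = 1)
  expect_equal(whole$per_stratum$auc, auc_on(s, y))

  two <- stratified_auc(s, y, c(rep("a", 150), rep("b", 150)),
                        B = 100, seed = 1)
  expect_equal(nrow(two$per_stratum), 2)
  expect_true(all(two$per_stratum$defined))

  # stratum with cases only: undefined and flagged
  strat <- ifelse(y == 1, "cases_only", "rest")
  mixed <- stratified_auc(s, y, strat, B = 100, seed = 1)
  row <- mixed$per_stratum[mixed$per_stratum$stratum == "cases_only", ]
  expect_false(row$defined)
  expect_true(row$flagged)
  expect_true(is.na(row$auc))

  # subtype framing: each subtype's cases vs all controls
  sub <- data.frame(subtype_a = as.integer(y == 1 & s > 1),
                    subtype_b = as.integer(y == 1 & s <= 1))
  bysub <- stratified_auc(s, y, sub, B = 100, seed = 1)
  expect_equal(nrow(bysub$per_stratum), 2)
  expect_gt(bysub$per_stratum$auc[1], auc_on(s, y))  # high-score subtype
})

test_that("feature associations report Mann-Whitney p and matched effect sizes", {
  rec <- toy_records(n_per = 500, delta = 0, seed = 9)
  # planted 1-sd shift on stv
  rec$stv <- rec$stv + ifelse(rec$cohort == "APO", 1.5, 0)
  out <- feature_association_tests(rec)
  expect_lt(out$p_value[out$feature == "stv"], 0.001)
  expect_equal(out$direction[out$feature == "stv"], "APO higher")

  # rank-biserial equals 2*AUC - 1 for a skewed feature
  rec$most_lost_beats <- rlnorm(1000, log(10) +
                                  0.4 * (rec$cohort == "APO"), 0.8)
  out2 <- feature_association_tests(rec)
  row <- out2[out2$feature == "most_lost_beats", ]
  expect_equal(row$effect_type, "rank_biserial")
  a <- auc_on(rec$most_lost_beats, rec$cohort == "APO")
  expect_equal(row$effect_size, 2 * a - 1, tolerance = 1e-12)

  rec$basal_fhr <- 140
  expect_warning(out3 <- feature_association_tests(rec), "constant feature")
  expect_equal(out3$p_value[out3$feature == "basal_fhr"], 1)
})

test_that("association tests are calibrated under the null", {
  set.seed(10)
  pvals <- replicate(60, {
    rec <- data.frame(cohort = rep(c("NPO", "APO"), each = 100),
                      stv = rnorm(200))
    feature_association_tests(rec, features = "stv")$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(mean(pvals < 0.05), 0.15)
})
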