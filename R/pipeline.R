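# End-to-end orchestration: simulate -> extract -> QC -> match -> split ->
# transform -> train -> evaluate, as one configured, logged, seeded run.

#' Pipeline run configuration
#'
#' A single global seed fans out to per-stage seeds as
#' `seed * 8 + stage_offset` with offsets 1 (simulation), 2 (split), 3 (folds),
#' 4 (tuning), 5 (final fit), 6 (evaluation bootstrap), so each stage is
#' individually reproducible. QC thresholds default to the printed clinical
#' values (see [qc_thresholds()]).
#'
#' @param simulation A [sim_config()] (its own seed is overridden by the
#'   stage seed).
#' @param qc List: `thresholds` (see [qc_thresholds()]) and `max_days`.
#' @param matching List: `caliper` (`NULL` = 0.2 sd of the logit score).
#' @param split List: `fraction`.
#' @param transform List: `skew_threshold`.
#' @param model List: `families` to cross-validate, `k` folds, tuning
#'   `budget`, `final_family` (`NULL` = best by median CV AUC).
#' @param evaluation List: bootstrap resamples `B`.
#' @param seed Global integer seed.
#' @param output_dir Artifact directory, or `NULL` to skip writing.
#' @return Object of class `run_config`.
#' @export
run_config <- function(simulation = sim_config(),
                       qc = list(thresholds = qc_thresholds(), max_days = 7),
                       matching = list(caliper = NULL),
                       split = list(fraction = 0.8),
                       transform = list(skew_threshold = 1),
                       model = list(families = MODEL_FAMILIES, k = 10,
                                    budget = 10, final_family = NULL),
                       evaluation = list(B = 1000),
                       seed = 1,
                       output_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' @keywords internal
stage_seed <- function(cfg, offset) cfg$seed * 8L + offset

#' Serialise / restore a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `path` (writer); a `run_config` (reader).
#' @export
write_run_config <- function(config, path) {
  obj <- unclass(config)
  obj$simulation <- unclass(obj$simulation)
  # named vectors serialise as YAML sequences (names lost): write as a map
  obj$simulation$subtype_prevalences <-
    as.list(obj$simulation$subtype_prevalences)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::yaml.load_file(path)
  sim <- do.call(sim_config, obj$simulation[names(obj$simulation) %in%
                                              names(formals(sim_config))])
  do.call(run_config, c(list(simulation = sim),
                        obj[setdiff(names(obj), "simulation")]))
}

#' Run the full pipeline
#'
#' Executes every stage in order on simulated (or supplied) data and returns
#' an evaluation report plus a manifest recording the seed, a configuration
#' hash and stage-wise record counts. When `config$output_dir` is set, the
#' feature table, QC report, matching diagnostics, CV table and a JSON master
#' report are written there.
#'
#' @param config A [run_config()].
#' @param records Optional pre-extracted feature/cohort records (skips the
#'   simulation and extraction stages).
#' @return List of class `fhr_run`: `report` (an `fhr_evaluation`), `cv`
#'   (per-family fold AUCs), `comparison`, `importances` (when the final
#'   model is a tree ensemble), `transforms`, `model`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), records = NULL) {
  stopifnot(inherits(config, "run_config"))
  counts <- list()
  log_stage <- function(stage, msg) {
    message(sprintf("[%s] %s", stage, msg))
  }

  if (is.null(records)) {
    sim_cfg <- config$simulation
    sim_cfg$seed <- stage_seed(config, 1L)
    if (sim_cfg$n_apo == 0 || sim_cfg$n_npo == 0) {
      stop("cohort stage failed: both cohorts must be non-empty (n_npo = ",
           sim_cfg$n_npo, ", n_apo = ", sim_cfg$n_apo, ")")
    }
    log_stage("simulate", sprintf("generating %d NPO + %d APO traces",
                                  sim_cfg$n_npo, sim_cfg$n_apo))
    sim <- simulate_cohort(sim_cfg)
    counts$simulated <- length(sim$traces)
    log_stage("extract", "extracting the seven FHR features")
    features <- extract_features_all(sim$traces)
    base_records <- sim$records
  } else {
    features <- records[, c("trace_id", .feature_cols), drop = FALSE]
    base_records <- records[, setdiff(names(records), .feature_cols),
                            drop = FALSE]
    counts$supplied <- nrow(records)
  }

  log_stage("qc", "applying plausibility and cohort-construction filters")
  qc_out <- run_qc(base_records, features,
                   thresholds = config$qc$thresholds,
                   max_days = config$qc$max_days)
  counts$post_qc <- nrow(qc_out$records)
  if (!counts$post_qc) stop("qc stage failed: no records retained")

  log_stage("match", "propensity-score matching without replacement")
  ps <- estimate_propensity(qc_out$records)
  mt <- match_without_replacement(qc_out$records, ps,
                                  caliper = config$matching$caliper)
  counts$post_match <- nrow(mt$records)
  if (counts$post_match < 20) {
    stop("matching stage failed: too few matched records (",
         counts$post_match, ")")
  }

  log_stage("split", sprintf("stratified %d:%d split",
                             round(100 * config$split$fraction),
                             round(100 * (1 - config$split$fraction))))
  sp <- stratified_split(mt$records, fraction = config$split$fraction,
                         seed = stage_seed(config, 2L))
  counts$train <- nrow(sp$train)
  counts$validation <- nrow(sp$validation)

  log_stage("transform", "fitting feature transforms on training data")
  tf <- fit_transforms(sp$train, skew_threshold = config$transform$skew_threshold)
  train_t <- apply_transforms(tf, sp$train)
  valid_t <- suppressMessages(apply_transforms(tf, sp$validation))

  log_stage("train", sprintf("tuning %d families, %d-fold CV, budget %d",
                             length(config$model$families), config$model$k,
                             config$model$budget))
  folds <- make_folds(train_t, k = config$model$k,
                      seed = stage_seed(config, 3L))
  cv_results <- list()
  tuned <- list()
  for (fam in config$model$families) {
    tn <- tune(fam, train_t, folds, budget = config$model$budget,
               seed = stage_seed(config, 4L))
    tuned[[fam]] <- tn$best_hp
    cv_results[[fam]] <- cross_validate(fam, train_t, folds, tn$best_hp,
                                        seed = stage_seed(config, 4L))
    log_stage("train", sprintf("%s: mean CV AUC %.3f", fam,
                               mean(cv_results[[fam]]$fold_auc)))
  }
  comparison <- if (length(cv_results) > 1) compare_models(cv_results) else NULL
  final_family <- config$model$final_family
  if (is.null(final_family)) {
    med <- vapply(cv_results, function(r) stats::median(r$fold_auc), numeric(1))
    final_family <- names(which.max(med))
  }
  log_stage("train", paste("final model:", final_family))
  model <- fit_final(final_family, train_t, tuned[[final_family]],
                     seed = stage_seed(config, 5L))
  importances <- if (final_family %in% c("random_forest",
                                         "gradient_boosted_trees")) {
    feature_importances(model)
  } else NULL

  log_stage("evaluate", "evaluating on the validation set")
  report <- evaluate_model(model, valid_t, B = config$evaluation$B,
                           seed = stage_seed(config, 6L))
  associations <- feature_association_tests(train_t)

  cfg_hash <- substr(digest_config(config), 1, 16)
  manifest <- list(seed = config$seed, config_hash = cfg_hash,
                   final_family = final_family, counts = counts)
  out <- structure(list(report = report, cv = cv_results,
                        comparison = comparison, importances = importances,
                        associations = associations, transforms = tf,
                        model = model, matching = mt[c("pairs", "balance")],
                        qc_log = qc_out$log, manifest = manifest),
                   class = "fhr_run")
  if (!is.null(config$output_dir)) {
    write_run_artifacts(out, features, qc_out, config)
  }
  out
}

#' @keywords internal
#' Stable hash of the configuration (FNV-1a over its deparsed form).
digest_config <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

#' @keywords internal
write_run_artifacts <- function(run, features, qc_out, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  od <- config$output_dir
  write_feature_table(features, file.path(od, "features.csv"))
  utils::write.csv(qc_out$qc, file.path(od, "qc_report.csv"), row.names = FALSE)
  utils::write.csv(run$matching$balance, file.path(od, "matching_balance.csv"),
                   row.names = FALSE)
  cv_tab <- do.call(rbind, lapply(names(run$cv), function(fam) {
    data.frame(family = fam, fold = seq_along(run$cv[[fam]]$fold_auc),
               auc = run$cv[[fam]]$fold_auc)
  }))
  utils::write.csv(cv_tab, file.path(od, "cv_auc.csv"), row.names = FALSE)
  utils::write.csv(run$report$operating_points,
                   file.path(od, "operating_points.csv"), row.names = FALSE)
  utils::write.csv(run$report$decision_curve$curve,
                   file.path(od, "decision_curve.csv"), row.names = FALSE)
  master <- list(
    manifest = run$manifest,
    auc = run$report$auc, auc_ci = as.list(run$report$auc_ci),
    brier = run$report$brier,
    operating_points = run$report$operating_points,
    auc_by_week = run$report$auc_by_week$per_stratum,
    auc_by_subtype = if (!is.null(run$report$auc_by_subtype)) {
      run$report$auc_by_subtype$per_stratum
    },
    importances = as.list(run$importances),
    cv_mean_auc = lapply(run$cv, function(r) mean(r$fold_auc))
  )
  jsonlite::write_json(master, file.path(od, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(od)
}

#' @export
print.fhr_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<fhr_run seed=%d final=%s | train %d / validation %d | AUC %.3f Brier %.3f>\n",
              m$seed, m$final_family, m$counts$train, m$counts$validation,
              x$report$auc, x$report$brier))
  invisible(x)
}
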