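# Plausibility filters and cohort-construction rules. All inequalities are
# strict, exactly as printed clinically: boundary values are retained.

#' Default plausibility thresholds
#'
#' A trace is excluded when it shows more than 30% signal loss, a basal FHR
#' below 100 or above 180 bpm, more than 1 acceleration per analysed minute,
#' more than 125 most lost beats, or an STV below 2 or above 30 ms.
#'
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function() {
  list(max_signal_loss_pct = 30,
       basal_min = 100, basal_max = 180,
       max_accel_per_min = 1,
       max_most_lost_beats = 125,
       stv_min = 2, stv_max = 30)
}

#' Plausibility filter for extracted feature vectors
#'
#' Applies the physiological plausibility rules to each feature row. The
#' acceleration-rate rule uses the analysed (<= 60 min) duration as its
#' denominator because the features themselves are computed on that window.
#' The most-lost-beats rule is evaluated on the capped window for the same
#' reason.
#'
#' @param features Feature data frame from [extract_features_all()].
#' @param thresholds See [qc_thresholds()].
#' @return Data frame `trace_id, passed, failed_rules` where `failed_rules`
#'   is a `;`-separated list of tripped rule identifiers (`passed` is `TRUE`
#'   iff the list is empty).
#' @export
plausibility_filter <- function(features, thresholds = qc_thresholds()) {
  th <- thresholds
  rules <- list(
    signal_loss = features$signal_loss_pct > th$max_signal_loss_pct,
    basal_low = features$basal_fhr < th$basal_min,
    basal_high = features$basal_fhr > th$basal_max,
    accel_rate = features$accelerations / features$analysed_duration_min >
      th$max_accel_per_min,
    most_lost_beats = features$most_lost_beats > th$max_most_lost_beats,
    stv_low = features$stv < th$stv_min,
    stv_high = features$stv > th$stv_max
  )
  failed <- vapply(seq_len(nrow(features)), function(i) {
    paste(names(rules)[vapply(rules, `[`, logical(1), i)], collapse = ";")
  }, character(1))
  data.frame(trace_id = features$trace_id,
             passed = failed == "",
             failed_rules = failed,
             stringsAsFactors = FALSE)
}

#' Keep only the first trace per pregnancy per gestational week
#'
#' When a pregnancy has more than one trace within a completed gestational
#' week, only the first (by `acquisition_order`, then by gestational age) is
#' retained, to avoid bias from repeat recordings prompted by findings on the
#' initial trace.
#'
#' @param records Cohort records carrying `pregnancy_id`,
#'   `gestational_age_days` and `acquisition_order`.
#' @return Filtered records, original ordering preserved.
#' @export
first_trace_per_week <- function(records) {
  need <- c("pregnancy_id", "gestational_age_days", "acquisition_order")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("validation error: records lack ordering key(s) ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyNA(records$acquisition_order)) {
    stop("validation error: acquisition_order contains missing values")
  }
  week <- records$gestational_age_days %/% 7
  key <- paste(records$pregnancy_id, week)
  ord <- order(records$acquisition_order, records$gestational_age_days)
  keep_ids <- !duplicated(key[ord])
  keep <- logical(nrow(records))
  keep[ord] <- keep_ids
  records[keep, , drop = FALSE]
}

#' Exclude APO traces acquired long before delivery
#'
#' Adverse-outcome traces acquired more than `max_days` before delivery are
#' removed (temporal misclassification guard); normal-outcome records are
#' untouched. The inequality is strict: a trace exactly `max_days` before
#' delivery is retained.
#'
#' @param records Cohort records.
#' @param max_days Window length in days (default 7).
#' @return Filtered records.
#' @export
temporal_window_filter <- function(records, max_days = 7) {
  apo <- records$cohort == "APO"
  dbd <- records$days_before_delivery
  if (any(apo & is.na(dbd))) {
    stop("validation error: APO record(s) lack days_before_delivery: ",
         paste(utils::head(records$trace_id[apo & is.na(dbd)], 3), collapse = ", "))
  }
  drop <- apo & dbd > max_days
  records[!drop, , drop = FALSE]
}

#' Apply all QC stages and report exclusions
#'
#' Runs [plausibility_filter()], [first_trace_per_week()] and
#' [temporal_window_filter()] and returns the retained records together with
#' an auditable exclusion log.
#'
#' @param records Cohort records (with `pregnancy_id`/`acquisition_order`).
#' @param features Feature rows aligned by `trace_id`.
#' @param thresholds See [qc_thresholds()].
#' @param max_days Temporal window for APO traces.
#' @return List with `records` (retained, joined with features), `qc` (the
#'   per-trace plausibility report) and `log` (data frame of exclusions with
#'   rule identifiers).
#' @export
run_qc <- function(records, features, thresholds = qc_thresholds(),
                   max_days = 7) {
  qc <- plausibility_filter(features, thresholds)
  log <- data.frame(trace_id = character(), rule = character(),
                    stringsAsFactors = FALSE)
  bad <- qc[!qc$passed, , drop = FALSE]
  if (nrow(bad)) {
    log <- rbind(log, data.frame(trace_id = bad$trace_id,
                                 rule = bad$failed_rules))
  }
  keep <- records$trace_id %in% qc$trace_id[qc$passed]
  rec <- records[keep, , drop = FALSE]

  rec2 <- first_trace_per_week(rec)
  dropped <- setdiff(rec$trace_id, rec2$trace_id)
  if (length(dropped)) {
    log <- rbind(log, data.frame(trace_id = dropped, rule = "repeat_in_week"))
  }
  rec3 <- temporal_window_filter(rec2, max_days)
  dropped <- setdiff(rec2$trace_id, rec3$trace_id)
  if (length(dropped)) {
    log <- rbind(log, data.frame(trace_id = dropped, rule = "acquired_gt_7d_before_delivery"))
  }
  out <- merge(rec3, features, by = "trace_id", sort = FALSE)
  list(records = out, qc = qc, log = log)
}
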