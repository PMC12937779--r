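#' @keywords internal
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.cohort_required_cols <- c("trace_id", "cohort", "gestational_age_days",
                           "fetal_sex", "duration_min", "days_before_delivery")

.feature_cols <- c("basal_fhr", "accelerations", "decelerations",
                   "most_lost_beats", "stv", "high_variation_min",
                   "low_variation_min", "analysed_duration_min",
                   "signal_loss_pct")

#' Read an FHR trace from CSV
#'
#' The trace dialect is a headed CSV with columns `time_s,fhr_bpm,missing`.
#' `missing` is 0/1; missing rows may carry `NA` in `fhr_bpm`. Malformed rows
#' are reported with their line numbers (header = line 1) and the reader
#' rejects rather than coercing invalid values.
#'
#' @param path Path to a trace CSV file.
#' @param trace_id Identifier to attach; defaults to the file name without
#'   extension.
#' @param metadata Optional metadata list (see [fhr_trace()]).
#' @return An [fhr_trace()].
#' @export
read_trace <- function(path, trace_id = NULL, metadata = list()) {
  if (!file.exists(path)) stop("trace file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "fhr_bpm", "missing")
  if (!identical(names(df)[seq_along(need)], need)) {
    stop("parse error in ", path, ": expected columns ",
         paste(need, collapse = ","), " but found ",
         paste(names(df), collapse = ","))
  }
  if (nrow(df) == 0L) stop("parse error in ", path, ": no data rows")
  lines <- seq_len(nrow(df)) + 1L
  if (!is.numeric(df$time_s) || anyNA(df$time_s)) {
    bad <- lines[!is.finite(suppressWarnings(as.numeric(df$time_s)))]
    stop("parse error in ", path, ": non-numeric time_s at line(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  back <- which(diff(df$time_s) <= 0)
  if (length(back)) {
    stop("parse error in ", path, ": time_s not strictly increasing at line(s) ",
         paste(utils::head(lines[back + 1L], 5), collapse = ", "))
  }
  if (!all(df$missing %in% c(0, 1))) {
    bad <- lines[!df$missing %in% c(0, 1)]
    stop("parse error in ", path, ": missing flag must be 0/1 at line(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  miss <- df$missing == 1
  fhr <- suppressWarnings(as.numeric(df$fhr_bpm))
  bad_fhr <- !miss & (is.na(fhr) | !is.finite(fhr) | fhr <= 0)
  if (any(bad_fhr)) {
    stop("parse error in ", path,
         ": non-missing fhr_bpm must be a finite positive number at line(s) ",
         paste(utils::head(lines[bad_fhr], 5), collapse = ", "))
  }
  if (is.null(trace_id)) trace_id <- sub("\\.[^.]*$", "", basename(path))
  dt <- diff(df$time_s)
  rate <- if (length(dt)) 1 / stats::median(dt) else 4
  fhr_trace(trace_id, df$time_s, fhr, miss, sampling_rate = rate,
            metadata = metadata)
}

#' Write an FHR trace to CSV
#'
#' Inverse of [read_trace()]; the round-trip is lossless on values (17
#' significant digits). Missing samples are written with `fhr_bpm = NA` and
#' `missing = 1`.
#'
#' @param trace An [fhr_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "fhr_trace"))
  fhr <- trace$fhr_bpm
  fhr[trace$missing_mask] <- NA_real_
  df <- data.frame(time_s = fmt_num(trace$time_s),
                   fhr_bpm = fmt_num(fhr),
                   missing = as.integer(trace$missing_mask))
  tryCatch(
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop("I/O error writing trace to ", path, ": ",
                             conditionMessage(e))
  )
  invisible(path)
}

#' @keywords internal
validate_cohort_table <- function(df, path = "<data>") {
  missing_cols <- setdiff(.cohort_required_cols, names(df))
  if (length(missing_cols)) {
    stop("validation error in ", path, ": missing required column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df)) {
    if (!all(df$cohort %in% c("NPO", "APO"))) {
      stop("validation error in ", path,
           ": cohort must be 'NPO' or 'APO' (outcome label missing or invalid)")
    }
    if (!all(df$fetal_sex %in% c("male", "female"))) {
      stop("validation error in ", path, ": unknown fetal_sex value '",
           setdiff(unique(df$fetal_sex), c("male", "female"))[1], "'")
    }
    num_cols <- c("gestational_age_days", "duration_min")
    for (cc in num_cols) {
      v <- df[[cc]]
      if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)) || any(v <= 0)) {
        stop("validation error in ", path, ": column ", cc,
             " must be finite, positive and complete")
      }
    }
    apo <- df$cohort == "APO"
    dbd <- df$days_before_delivery
    if (!is.numeric(dbd)) dbd <- suppressWarnings(as.numeric(dbd))
    if (any(apo & is.na(dbd))) {
      stop("validation error in ", path,
           ": APO records must carry days_before_delivery")
    }
    sub_cols <- grep("^subtype_", names(df), value = TRUE)
    for (cc in sub_cols) {
      if (!all(df[[cc]] %in% c(0, 1))) {
        stop("validation error in ", path, ": ", cc, " must be 0/1")
      }
    }
    if (length(sub_cols) && any(apo & rowSums(df[, sub_cols, drop = FALSE]) < 1)) {
      stop("validation error in ", path,
           ": every APO record must carry at least one adverse-outcome subtype")
    }
  }
  invisible(df)
}

#' Read a cohort table
#'
#' A cohort table is a headed CSV with one row per trace:
#' `trace_id,cohort,gestational_age_days,fetal_sex,duration_min,`
#' `days_before_delivery,subtype_*` plus optional bookkeeping columns
#' (`pregnancy_id`, `acquisition_order`). `cohort` is `NPO` (normal pregnancy
#' outcome) or `APO` (preterm adverse pregnancy outcome);
#' `days_before_delivery` is required for APO records and may be `NA` for NPO.
#'
#' @param path Path to the CSV.
#' @return A data frame of validated cohort records.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("cohort table does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort_table(df, path)
  df
}

#' Write a cohort table
#'
#' @param records Data frame of cohort records (see [read_cohort_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(records, path) {
  validate_cohort_table(records, "<records>")
  out <- records
  for (cc in names(out)) {
    if (is.numeric(out[[cc]]) && !all(out[[cc]] %% 1 == 0, na.rm = TRUE)) {
      out[[cc]] <- fmt_num(out[[cc]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a feature table
#'
#' A feature table holds the seven extracted FHR features plus the analysed
#' duration and signal-loss percentage, one row per trace. Numeric values are
#' written at 17 significant digits so the round-trip is lossless.
#'
#' @param records Data frame containing `trace_id` and the feature columns.
#' @param path Output path.
#' @return `path`, invisibly (writer); data frame (reader).
#' @export
write_feature_table <- function(records, path) {
  missing_cols <- setdiff(c("trace_id", .feature_cols), names(records))
  if (length(missing_cols)) {
    stop("validation error: feature table missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  out <- records
  for (cc in .feature_cols) out[[cc]] <- fmt_num(out[[cc]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("trace_id", .feature_cols), names(df))
  if (length(missing_cols)) {
    stop("parse error in ", path, ": feature table missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  for (cc in .feature_cols) {
    if (!is.numeric(df[[cc]]) || anyNA(df[[cc]])) {
      stop("parse error in ", path, ": column ", cc, " must be numeric and complete")
    }
  }
  df
}
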