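#' Construct a fetal heart rate trace
#'
#' An `fhr_trace` holds time-stamped fetal heart rate (FHR) samples in beats
#' per minute together with an explicit missing-sample mask and acquisition
#' metadata. Time coordinates are 0-based seconds from the start of the
#' recording; intervals are treated as half-open `[onset, offset)`.
#'
#' @param trace_id Character scalar identifying the trace.
#' @param time_s Numeric vector of strictly increasing sample times (seconds).
#' @param fhr_bpm Numeric vector of FHR samples (bpm). Samples flagged missing
#'   may hold any value (a sentinel `NA` is written on export); non-missing
#'   samples must be finite and positive.
#' @param missing_mask Logical vector, `TRUE` where the signal was lost.
#' @param sampling_rate Sampling rate in Hz.
#' @param metadata Named list of acquisition metadata. Recognised fields:
#'   `gestational_age_days`, `fetal_sex` (`"male"` or `"female"`),
#'   `duration_min`, `days_before_delivery`, `pregnancy_id`, `cohort`.
#'
#' @return An object of class `fhr_trace`.
#' @export
fhr_trace <- function(trace_id, time_s, fhr_bpm,
                      missing_mask = rep(FALSE, length(fhr_bpm)),
                      sampling_rate = 4,
                      metadata = list()) {
  if (!is.character(trace_id) || length(trace_id) != 1L || is.na(trace_id)) {
    stop("trace_id must be a single non-missing character string")
  }
  n <- length(time_s)
  if (length(fhr_bpm) != n || length(missing_mask) != n) {
    stop("time_s, fhr_bpm and missing_mask must have equal length (got ",
         n, ", ", length(fhr_bpm), ", ", length(missing_mask), ")")
  }
  if (n == 0L) stop("trace must contain at least one sample")
  if (anyNA(time_s) || any(diff(time_s) <= 0)) {
    stop("time_s must be strictly increasing with no missing values")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("invalid-config: sampling_rate must be a single positive number")
  }
  missing_mask <- as.logical(missing_mask)
  if (anyNA(missing_mask)) stop("missing_mask must be TRUE/FALSE with no NA")
  missing_mask <- missing_mask | is.na(fhr_bpm)
  valid <- fhr_bpm[!missing_mask]
  if (length(valid) && (any(!is.finite(valid)) || any(valid <= 0))) {
    stop("non-missing fhr_bpm values must be finite and > 0")
  }
  if (!is.null(metadata$fetal_sex) &&
      !metadata$fetal_sex %in% c("male", "female")) {
    stop("metadata$fetal_sex must be 'male' or 'female', got '",
         metadata$fetal_sex, "'")
  }
  structure(
    list(trace_id = trace_id,
         time_s = as.numeric(time_s),
         fhr_bpm = as.numeric(fhr_bpm),
         missing_mask = missing_mask,
         sampling_rate = sampling_rate,
         metadata = metadata),
    class = "fhr_trace"
  )
}

#' @export
print.fhr_trace <- function(x, ...) {
  n <- length(x$time_s)
  loss <- round(100 * mean(x$missing_mask), 1)
  cat(sprintf("<fhr_trace %s: %d samples @ %g Hz, %.1f min, %.1f%% signal loss>\n",
              x$trace_id, n, x$sampling_rate,
              trace_duration_min(x), loss))
  invisible(x)
}

#' Trace duration in minutes
#'
#' Duration is the span from time zero to one sample period past the last
#' timestamp, so that a trace of `n` regularly spaced samples lasts
#' `n / sampling_rate` seconds.
#'
#' @param trace An `fhr_trace`.
#' @return Duration in minutes.
#' @export
trace_duration_min <- function(trace) {
  (trace$time_s[length(trace$time_s)] + 1 / trace$sampling_rate) / 60
}

#' Truncate a trace to its first `minutes` minutes
#'
#' @param trace An `fhr_trace`.
#' @param minutes Window length in minutes; samples with `time_s` in
#'   `[0, minutes * 60)` are kept.
#' @return An `fhr_trace` covering at most `minutes` minutes.
#' @export
truncate_trace <- function(trace, minutes) {
  keep <- trace$time_s < minutes * 60
  if (!any(keep)) stop("truncation window contains no samples")
  fhr_trace(trace$trace_id,
            trace$time_s[keep], trace$fhr_bpm[keep], trace$missing_mask[keep],
            trace$sampling_rate, trace$metadata)
}
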