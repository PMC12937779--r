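# Seven-feature extraction for antepartum FHR traces: baseline fitting,
# acceleration/deceleration detection, lost beats, short-term variation and
# high/low-variation episodes. Analysis is capped at the first 60 minutes.

#' Default feature-extraction parameters
#'
#' @param cap_min Analysis cap in minutes; features are not extracted beyond
#'   this point of the trace.
#' @param baseline_window_min Width (minutes) of the moving window used by the
#'   iterative trimmed-mean baseline.
#' @param baseline_trim_bpm Samples deviating more than this from the current
#'   baseline estimate are excluded from the next averaging pass.
#' @param baseline_tol_bpm Convergence tolerance of the baseline iteration.
#' @param baseline_max_iter Maximum baseline iterations.
#' @param accel_bpm,accel_s Acceleration criterion: deviation of at least
#'   `accel_bpm` above baseline lasting longer than `accel_s` seconds.
#' @param decel_bpm,decel_s Primary deceleration criterion: at least
#'   `decel_bpm` below baseline sustained for more than `decel_s` seconds.
#' @param decel_bpm2,decel_s2 Secondary deceleration criterion: at least
#'   `decel_bpm2` below baseline for more than `decel_s2` seconds.
#' @param gap_bridge_s Sub-threshold gaps shorter than this (seconds) inside a
#'   run are bridged so sampling noise does not split one physiological event.
#' @param epoch_s Epoch length for pulse-interval averaging (3.75 s gives the
#'   conventional 16 epochs per minute).
#' @param high_variation_ms Minute-level pulse-interval range at or above
#'   which a minute qualifies as high variation.
#' @param low_variation_ms Minute-level pulse-interval range at or below which
#'   a minute qualifies as low variation.
#' @param episode_window,episode_need An episode requires at least
#'   `episode_need` qualifying minutes within `episode_window` consecutive
#'   minutes, extended maximally.
#' @param max_minute_missing Minutes with more than this fraction of missing
#'   samples are excluded from STV and episode classification.
#' @return Named list of parameters.
#' @export
feature_params <- function(cap_min = 60,
                           baseline_window_min = 10,
                           baseline_trim_bpm = 10,
                           baseline_tol_bpm = 0.1,
                           baseline_max_iter = 20,
                           accel_bpm = 10, accel_s = 15,
                           decel_bpm = 20, decel_s = 30,
                           decel_bpm2 = 10, decel_s2 = 60,
                           gap_bridge_s = 5,
                           epoch_s = 3.75,
                           high_variation_ms = 32,
                           low_variation_ms = 30,
                           episode_window = 6, episode_need = 5,
                           max_minute_missing = 0.5) {
  as.list(environment())
}

#' @keywords internal
roll_sum <- function(v, half) {
  n <- length(v)
  cs <- c(0, cumsum(v))
  i <- seq_len(n)
  a <- pmax(1L, i - half)
  b <- pmin(n, i + half)
  cs[b + 1L] - cs[a]
}

#' Fit the FHR baseline
#'
#' The baseline is the average FHR excluding any major deviations. It is
#' estimated by an iterative trimmed moving average: a centred windowed mean
#' in which samples deviating more than `baseline_trim_bpm` from the current
#' estimate are excluded, iterated to convergence. The result is smooth and
#' insensitive to transient accelerations/decelerations.
#'
#' @param trace An [fhr_trace()].
#' @param params See [feature_params()].
#' @return Numeric vector of per-sample baseline values (bpm), finite
#'   everywhere (gaps are linearly interpolated).
#' @export
fit_baseline <- function(trace, params = feature_params()) {
  x <- trace$fhr_bpm
  w0 <- !trace$missing_mask
  rate <- trace$sampling_rate
  if (sum(w0) < 60 * rate) {
    stop("extraction error: need at least one non-missing minute of signal to fit a baseline")
  }
  half <- max(1L, as.integer(round(params$baseline_window_min * 60 * rate / 2)))
  xz <- ifelse(w0, x, 0)
  est <- rep(stats::median(x[w0]), length(x))
  for (iter in seq_len(params$baseline_max_iter)) {
    keep <- w0 & abs(x - est) <= params$baseline_trim_bpm
    if (!any(keep)) keep <- w0  # all samples trimmed: fall back to untrimmed pass
    num <- roll_sum(ifelse(keep, xz, 0), half)
    den <- roll_sum(as.numeric(keep), half)
    b <- num / den
    if (any(den == 0)) {
      idx <- which(den > 0)
      b <- stats::approx(idx, b[idx], xout = seq_along(x), rule = 2)$y
    }
    delta <- max(abs(b - est))
    est <- b
    if (delta < params$baseline_tol_bpm) break
  }
  est
}

#' @keywords internal
#' Maximal runs of TRUE in `qual`, bridging internal FALSE gaps shorter than
#' `max_gap` samples. Returns a 2-column matrix of start/end sample indices.
logical_runs <- function(qual, max_gap = 0L) {
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (nrow(runs) > 1L && max_gap > 0L) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap <- runs[i, 1] - merged[nrow(merged), 2] - 1L
      if (gap < max_gap) {
        merged[nrow(merged), 2] <- runs[i, 2]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  runs
}

#' Detect accelerations and decelerations
#'
#' An acceleration is a maximal run of samples at least `accel_bpm` above
#' baseline whose duration exceeds `accel_s` seconds. A deceleration is a
#' maximal run at least `decel_bpm2` below baseline that either contains a
#' stretch of at least `decel_bpm` below baseline sustained for more than
#' `decel_s` seconds, or itself lasts more than `decel_s2` seconds. Runs
#' separated by sub-threshold gaps shorter than `gap_bridge_s` are merged.
#'
#' @param trace An [fhr_trace()].
#' @param baseline Per-sample baseline from [fit_baseline()].
#' @param params See [feature_params()].
#' @return A data frame of events sorted by onset with columns `kind`
#'   (`"acceleration"`/`"deceleration"`), `onset_s`, `offset_s` (half-open),
#'   `peak_deviation_bpm` (signed) and `lost_beats` (decelerations; `NA` for
#'   accelerations).
#' @export
detect_events <- function(trace, baseline, params = feature_params()) {
  stopifnot(length(baseline) == length(trace$fhr_bpm))
  rate <- trace$sampling_rate
  t0 <- trace$time_s - trace$time_s[1]
  dev <- trace$fhr_bpm - baseline
  dev[trace$missing_mask] <- 0
  max_gap <- as.integer(floor(params$gap_bridge_s * rate))
  dur_of <- function(run) (run[2] - run[1] + 1L) / rate

  events <- list()
  acc_runs <- logical_runs(dev >= params$accel_bpm, max_gap)
  if (nrow(acc_runs)) {
    for (i in seq_len(nrow(acc_runs))) {
      run <- acc_runs[i, ]
      if (dur_of(run) > params$accel_s) {
        sl <- run[1]:run[2]
        events[[length(events) + 1L]] <- data.frame(
          kind = "acceleration",
          onset_s = t0[run[1]],
          offset_s = t0[run[2]] + 1 / rate,
          peak_deviation_bpm = max(dev[sl]),
          lost_beats = NA_real_
        )
      }
    }
  }
  dec_runs <- logical_runs(dev <= -params$decel_bpm2, max_gap)
  if (nrow(dec_runs)) {
    for (i in seq_len(nrow(dec_runs))) {
      run <- dec_runs[i, ]
      sl <- run[1]:run[2]
      deep <- logical_runs(dev[sl] <= -params$decel_bpm, max_gap)
      deep_ok <- nrow(deep) > 0 &&
        any((deep[, 2] - deep[, 1] + 1L) / rate > params$decel_s)
      if (deep_ok || dur_of(run) > params$decel_s2) {
        ev <- data.frame(
          kind = "deceleration",
          onset_s = t0[run[1]],
          offset_s = t0[run[2]] + 1 / rate,
          peak_deviation_bpm = min(dev[sl]),
          lost_beats = NA_real_
        )
        ev$lost_beats <- lost_beats(ev, trace, baseline)
        events[[length(events) + 1L]] <- ev
      }
    }
  }
  if (!length(events)) {
    return(data.frame(kind = character(), onset_s = numeric(),
                      offset_s = numeric(), peak_deviation_bpm = numeric(),
                      lost_beats = numeric()))
  }
  out <- do.call(rbind, events)
  out[order(out$onset_s), , drop = FALSE]
}

#' Lost beats of a deceleration
#'
#' Lost beats are the product of the duration of a deceleration and the
#' magnitude of its deviation below baseline, computed as the integrated area
#' between baseline and signal (bpm x minutes = beats). The integration extent
#' is the event run extended outward to where the deviation returns to
#' baseline, so the whole morphology of the dip is counted; for a rectangular
#' deceleration this equals depth times duration exactly.
#'
#' @param event One-row event data frame (see [detect_events()]); must be a
#'   deceleration.
#' @param trace An [fhr_trace()].
#' @param baseline Per-sample baseline.
#' @return Lost beats (>= 0).
#' @export
lost_beats <- function(event, trace, baseline) {
  if (!identical(event$kind, "deceleration")) {
    stop("contract violation: lost_beats is defined for decelerations only")
  }
  rate <- trace$sampling_rate
  t0 <- trace$time_s - trace$time_s[1]
  dev <- trace$fhr_bpm - baseline
  dev[trace$missing_mask] <- 0
  i1 <- which(t0 >= event$onset_s)[1]
  i2 <- max(which(t0 < event$offset_s))
  while (i1 > 1L && dev[i1 - 1L] < 0) i1 <- i1 - 1L
  n <- length(dev)
  while (i2 < n && dev[i2 + 1L] < 0) i2 <- i2 + 1L
  sum(pmax(0, -dev[i1:i2])) / rate / 60
}

#' Most lost beats
#'
#' Largest loss of beats due to a single deceleration in the trace; zero when
#' the trace has no decelerations.
#'
#' @param events Event data frame from [detect_events()].
#' @return Most lost beats (>= 0).
#' @export
most_lost_beats <- function(events) {
  lb <- events$lost_beats[events$kind == "deceleration"]
  if (!length(lb)) 0 else max(lb)
}

#' @keywords internal
#' Epoch-level pulse intervals (ms). Returns a list with per-epoch mean pulse
#' interval, validity flag (epoch and its minute at most `max_minute_missing`
#' missing) and the 0-based minute index of each epoch.
epoch_pulse_intervals <- function(trace, params) {
  rate <- trace$sampling_rate
  ep_len <- max(1L, as.integer(round(params$epoch_s * rate)))
  n_ep <- length(trace$fhr_bpm) %/% ep_len
  if (n_ep < 1L) {
    return(list(pi_ms = numeric(), valid = logical(), minute = integer()))
  }
  idx <- seq_len(n_ep * ep_len)
  pi_ms <- 60000 / trace$fhr_bpm[idx]
  pi_ms[trace$missing_mask[idx]] <- NA_real_
  m <- matrix(pi_ms, nrow = ep_len)
  miss <- matrix(trace$missing_mask[idx], nrow = ep_len)
  ep_pi <- colMeans(m, na.rm = TRUE)
  ep_missfrac <- colMeans(miss)
  minute <- (seq_len(n_ep) - 1L) %/% as.integer(round(60 / params$epoch_s))
  min_missfrac <- tapply(ep_missfrac, minute, mean)
  valid <- ep_missfrac <= params$max_minute_missing &
    min_missfrac[as.character(minute)] <= params$max_minute_missing &
    is.finite(ep_pi)
  list(pi_ms = ep_pi, valid = as.logical(valid), minute = minute,
       ep_len = ep_len)
}

#' Short-term variation (STV)
#'
#' STV is the mean absolute difference between successive pulse intervals
#' (60000 / FHR, ms), computed on fixed epochs (`epoch_s`, default 3.75 s)
#' whose value is the mean pulse interval of the epoch. Differences are taken
#' between adjacent valid epochs only; epochs overlapping a detected
#' deceleration and epochs in minutes with excessive signal loss are excluded.
#'
#' @param trace An [fhr_trace()].
#' @param events Optional event data frame; decelerations are masked out.
#' @param params See [feature_params()].
#' @return STV in milliseconds (>= 0).
#' @export
compute_stv <- function(trace, events = NULL, params = feature_params()) {
  ep <- epoch_pulse_intervals(trace, params)
  valid <- ep$valid
  if (!is.null(events) && nrow(events)) {
    dec <- events[events$kind == "deceleration", , drop = FALSE]
    if (nrow(dec)) {
      ep_onset <- (seq_along(ep$pi_ms) - 1L) * ep$ep_len / trace$sampling_rate
      ep_offset <- ep_onset + ep$ep_len / trace$sampling_rate
      for (i in seq_len(nrow(dec))) {
        valid <- valid & !(ep_offset > dec$onset_s[i] & ep_onset < dec$offset_s[i])
      }
    }
  }
  if (sum(valid) < 2L) {
    stop("extraction error: fewer than 2 valid epochs; cannot compute STV")
  }
  d <- diff(ep$pi_ms)
  ok <- valid[-length(valid)] & valid[-1]
  if (!any(ok)) {
    stop("extraction error: no adjacent pair of valid epochs; cannot compute STV")
  }
  mean(abs(d[ok]))
}

#' Minutes spent in high- and low-variation episodes
#'
#' Each complete minute is classified by the range of its epoch pulse
#' intervals: at or above `high_variation_ms` qualifies as high variation, at
#' or below `low_variation_ms` as low variation. An episode requires at least
#' `episode_need` qualifying minutes within any `episode_window` consecutive
#' minutes, extended maximally; only qualifying minutes inside such windows
#' are counted. A minute cannot count toward both kinds.
#'
#' @param trace An [fhr_trace()].
#' @param params See [feature_params()].
#' @return Named numeric vector `c(high_variation_min=, low_variation_min=)`.
#' @export
variation_episodes <- function(trace, params = feature_params()) {
  ep <- epoch_pulse_intervals(trace, params)
  per_min <- as.integer(round(60 / params$epoch_s))
  n_min <- length(ep$pi_ms) %/% per_min
  if (n_min < 1L) {
    return(c(high_variation_min = 0, low_variation_min = 0))
  }
  high_q <- logical(n_min)
  low_q <- logical(n_min)
  for (m in seq_len(n_min)) {
    sel <- ep$minute == (m - 1L) & ep$valid
    v <- ep$pi_ms[sel]
    if (length(v) < 2L) next  # minute invalid: too much signal loss
    r <- max(v) - min(v)
    if (r >= params$high_variation_ms) high_q[m] <- TRUE
    else if (r <= params$low_variation_ms) low_q[m] <- TRUE
  }
  mark <- function(q) {
    marked <- logical(length(q))
    w <- params$episode_window
    need <- params$episode_need
    if (length(q) < need) return(marked)
    w_eff <- min(w, length(q))
    for (i in seq_len(length(q) - w_eff + 1L)) {
      win <- i:(i + w_eff - 1L)
      if (sum(q[win]) >= need) marked[win] <- marked[win] | q[win]
    }
    marked
  }
  c(high_variation_min = sum(mark(high_q)),
    low_variation_min = sum(mark(low_q)))
}

#' Extract the seven FHR features from a trace
#'
#' Applies baseline fitting, event detection, lost-beats accounting, STV and
#' variation-episode classification to the first `cap_min` (default 60)
#' minutes of the trace. The basal FHR is the time-average of the fitted
#' baseline over the analysed window; signal loss is the percentage of
#' missing samples in that window.
#'
#' @param trace An [fhr_trace()].
#' @param params See [feature_params()].
#' @return One-row data frame with columns `trace_id`, `basal_fhr`,
#'   `accelerations`, `decelerations`, `most_lost_beats`, `stv`,
#'   `high_variation_min`, `low_variation_min`, `analysed_duration_min`,
#'   `signal_loss_pct`.
#' @export
extract_features <- function(trace, params = feature_params()) {
  stopifnot(inherits(trace, "fhr_trace"))
  if (all(trace$missing_mask)) {
    stop("extraction error: trace is entirely missing")
  }
  tr <- trace
  tr$time_s <- tr$time_s - tr$time_s[1]
  if (trace_duration_min(tr) > params$cap_min) {
    tr <- truncate_trace(tr, params$cap_min)
  }
  baseline <- fit_baseline(tr, params)
  events <- detect_events(tr, baseline, params)
  ve <- variation_episodes(tr, params)
  data.frame(
    trace_id = tr$trace_id,
    basal_fhr = mean(baseline),
    accelerations = sum(events$kind == "acceleration"),
    decelerations = sum(events$kind == "deceleration"),
    most_lost_beats = most_lost_beats(events),
    stv = compute_stv(tr, events, params),
    high_variation_min = unname(ve["high_variation_min"]),
    low_variation_min = unname(ve["low_variation_min"]),
    analysed_duration_min = trace_duration_min(tr),
    signal_loss_pct = 100 * mean(tr$missing_mask),
    stringsAsFactors = FALSE
  )
}

#' Extract features for a list of traces
#'
#' @param traces List of [fhr_trace()] objects.
#' @param params See [feature_params()].
#' @return Data frame with one row per trace.
#' @export
extract_features_all <- function(traces, params = feature_params()) {
  do.call(rbind, lapply(traces, extract_features, params = params))
}
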