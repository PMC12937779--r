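# Shared fixture builders and independent oracles. Everything is generated in
# code; no stored data.

FEATS <- c("basal_fhr", "accelerations", "decelerations", "most_lost_beats",
           "stv", "high_variation_min", "low_variation_min")

# A flat trace at `bpm` lasting `minutes`, 4 Hz.
flat_trace <- function(bpm = 140, minutes = 30, rate = 4, id = "flat") {
  n <- minutes * 60 * rate
  fhr_trace(id, (seq_len(n) - 1) / rate, rep(bpm, n), sampling_rate = rate)
}

# Add a plateau deviation of `dev` bpm over [onset, onset + dur) seconds.
with_plateau <- function(trace, dev, onset_s, dur_s, shape = c("rect", "triangle")) {
  shape <- match.arg(shape)
  t0 <- trace$time_s
  sel <- t0 >= onset_s & t0 < onset_s + dur_s
  w <- if (shape == "rect") 1 else {
    x <- (t0[sel] - onset_s) / dur_s
    1 - abs(2 * x - 1)
  }
  trace$fhr_bpm[sel] <- trace$fhr_bpm[sel] + dev * w
  trace
}

# Minimal cohort records for cohort/modeling tests: two Gaussian feature
# clouds with a location shift `delta` on `stv` and `high_variation_min`.
toy_records <- function(n_per = 60, delta = 1.5, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  cohort <- rep(c("NPO", "APO"), each = n_per)
  shift <- ifelse(cohort == "APO", delta, 0)
  data.frame(
    trace_id = sprintf("T%04d", seq_len(n)),
    pregnancy_id = sprintf("P%04d", seq_len(n)),
    cohort = cohort,
    gestational_age_days = sample(189:258, n, replace = TRUE),
    fetal_sex = sample(c("male", "female"), n, replace = TRUE),
    duration_min = runif(n, 35, 70),
    days_before_delivery = ifelse(cohort == "APO", sample(0:7, n, TRUE), NA),
    acquisition_order = 1L,
    basal_fhr = rnorm(n, 138, 4),
    accelerations = rpois(n, 4),
    decelerations = rpois(n, 1),
    most_lost_beats = rlnorm(n, log(12), 0.3),
    stv = rnorm(n, 8, 1.5) - shift,
    high_variation_min = pmax(0, rnorm(n, 7, 3) - 2 * shift),
    low_variation_min = pmax(0, rnorm(n, 2, 2) + 2 * shift),
    stringsAsFactors = FALSE
  )
}

# AUC convenience wrapper used across tests.
auc_on <- function(scores, labels) roc_and_auc(scores, as.integer(labels))$auc

# A feature row that passes every QC rule; fields overridden as needed.
nominal_features <- function(...) {
  base <- data.frame(trace_id = "t1", basal_fhr = 140, accelerations = 4,
                     decelerations = 1, most_lost_beats = 12, stv = 8,
                     high_variation_min = 6, low_variation_min = 2,
                     analysed_duration_min = 50, signal_loss_pct = 5,
                     stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# ---------------------------------------------------------------------------
# Independent exhaustive run-scan oracle for event detection: plain loops,
# no shared code with detect_events().
oracle_detect_events <- function(trace, baseline, params = feature_params()) {
  rate <- trace$sampling_rate
  t0 <- trace$time_s - trace$time_s[1]
  dev <- trace$fhr_bpm - baseline
  dev[trace$missing_mask] <- 0
  n <- length(dev)
  max_gap <- floor(params$gap_bridge_s * rate)

  scan_runs <- function(flag) {
    runs <- list()
    i <- 1
    while (i <= n) {
      if (flag[i]) {
        j <- i
        while (j < n && flag[j + 1]) j <- j + 1
        runs[[length(runs) + 1]] <- c(i, j)
        i <- j + 1
      } else i <- i + 1
    }
    # bridge gaps strictly shorter than max_gap samples
    if (length(runs) > 1) {
      out <- list(runs[[1]])
      for (k in 2:length(runs)) {
        prev <- out[[length(out)]]
        gap <- runs[[k]][1] - prev[2] - 1
        if (gap < max_gap) {
          out[[length(out)]][2] <- runs[[k]][2]
        } else out[[length(out) + 1]] <- runs[[k]]
      }
      runs <- out
    }
    runs
  }

  res <- list()
  for (run in scan_runs(dev >= params$accel_bpm)) {
    if ((run[2] - run[1] + 1) / rate > params$accel_s) {
      res[[length(res) + 1]] <- data.frame(
        kind = "acceleration", onset_s = t0[run[1]],
        offset_s = t0[run[2]] + 1 / rate)
    }
  }
  for (run in scan_runs(dev <= -params$decel_bpm2)) {
    seg <- dev[run[1]:run[2]]
    deep_ok <- FALSE
    for (dr in scan_runs2(seg <= -params$decel_bpm, max_gap)) {
      if ((dr[2] - dr[1] + 1) / rate > params$decel_s) deep_ok <- TRUE
    }
    if (deep_ok || (run[2] - run[1] + 1) / rate > params$decel_s2) {
      res[[length(res) + 1]] <- data.frame(
        kind = "deceleration", onset_s = t0[run[1]],
        offset_s = t0[run[2]] + 1 / rate)
    }
  }
  if (!length(res)) {
    return(data.frame(kind = character(), onset_s = numeric(),
                      offset_s = numeric()))
  }
  out <- do.call(rbind, res)
  out[order(out$onset_s), , drop = FALSE]
}

# run scan over a short logical vector (helper for the oracle's deep check)
scan_runs2 <- function(flag, max_gap) {
  n <- length(flag)
  runs <- list()
  i <- 1
  while (i <= n) {
    if (flag[i]) {
      j <- i
      while (j < n && flag[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (length(runs) > 1) {
    out <- list(runs[[1]])
    for (k in 2:length(runs)) {
      prev <- out[[length(out)]]
      gap <- runs[[k]][1] - prev[2] - 1
      if (gap < max_gap) {
        out[[length(out)]][2] <- runs[[k]][2]
      } else out[[length(out) + 1]] <- runs[[k]]
    }
    runs <- out
  }
  runs
}

# Brute-force episode marker: every qualifying minute inside any window of
# `w` consecutive minutes containing >= `need` qualifying minutes.
oracle_mark_episode_minutes <- function(q, w = 6, need = 5) {
  n <- length(q)
  marked <- rep(FALSE, n)
  if (n < need) return(sum(marked))
  w_eff <- min(w, n)
  for (i in seq_len(n - w_eff + 1)) {
    win <- i:(i + w_eff - 1)
    if (sum(q[win]) >= need) marked[win][q[win]] <- TRUE
  }
  sum(marked)
}
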