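# Synthetic antepartum FHR cohort generator with planted ground truth.
#
# Traces are built on the pulse-interval (ms) scale: a slow amplitude-
# modulated oscillation (fetal behavioural-state cycling) plus an AR(1)
# jitter, rescaled minute-by-minute so that each minute's epoch pulse-interval
# range is pinned exactly. This makes short-term variation and high/low
# variation episode minutes directly controllable from the configured cohort
# feature targets. Accelerations and decelerations are planted on the bpm
# scale with margins above the detection thresholds.

#' Default per-cohort feature targets
#'
#' Target medians for the seven extracted features in each cohort. Values
#' follow the published group medians where the extraction definitions make
#' them attainable; decelerations, most lost beats and episode minutes are
#' adjusted to the nearest attainable medians (a detected deceleration cannot
#' lose fewer than about 11 beats, and an episode cannot be shorter than 5
#' minutes) while preserving every direction of group difference: the normal
#' outcome (NPO) cohort has more accelerations, more high-variation minutes
#' and higher STV; the adverse outcome (APO) cohort has a higher basal rate,
#' more decelerations, more low-variation minutes and more lost beats.
#'
#' @return Named list with elements `NPO` and `APO`, each a list of target
#'   medians: `basal_fhr` (bpm), `accelerations`, `decelerations` (counts),
#'   `most_lost_beats` (beats), `stv` (ms), `high_variation_min`,
#'   `low_variation_min` (minutes).
#' @export
default_feature_targets <- function() {
  list(
    NPO = list(basal_fhr = 138, accelerations = 5, decelerations = 1,
               most_lost_beats = 12, stv = 9,
               high_variation_min = 7, low_variation_min = 0),
    APO = list(basal_fhr = 139, accelerations = 3, decelerations = 2,
               most_lost_beats = 15, stv = 7,
               high_variation_min = 0, low_variation_min = 5)
  )
}

#' Default adverse-outcome subtype prevalences
#'
#' Ten predefined adverse-outcome criteria with realistic class imbalance;
#' every APO record receives at least one label. Subtypes co-occur (see
#' `subtype_correlation` in [sim_config()]).
#'
#' @return Named numeric vector of per-subtype probabilities.
#' @export
default_subtype_prevalences <- function() {
  c(acidaemia = 0.22,
    stillbirth = 0.05,
    asphyxia = 0.05,
    birthweight_le_3rd_centile = 0.30,
    special_care_ge_7d = 0.17,
    hie = 0.01,
    low_apgar = 0.10,
    neonatal_sepsis = 0.08,
    perinatal_infection = 0.07,
    respiratory_condition = 0.35)
}

#' Simulation configuration
#'
#' @param n_npo,n_apo Cohort sizes (normal / preterm adverse outcome).
#' @param gestation_range Gestational age bounds in days (27+0 to 36+6 weeks
#'   is 189 to 258 days).
#' @param duration_minutes_range Trace duration range (minutes); durations
#'   beyond 60 minutes are generated but features are capped at 60.
#' @param sampling_rate Sampling rate in Hz (4 Hz is standard
#'   cardiotocograph output).
#' @param seed Base seed; trace `i` uses `seed + i`.
#' @param cohort_feature_targets See [default_feature_targets()].
#' @param signal_loss_fraction_range Range of the per-trace fraction of
#'   samples replaced by the missing marker.
#' @param subtype_prevalences See [default_subtype_prevalences()].
#' @param subtype_correlation Gaussian-copula correlation used to make
#'   subtypes co-occur.
#' @param p_male Probability of male fetal sex, allocated by exact counts.
#' @param extra_high_episode_prob,extra_low_episode_prob Probability that a
#'   trace whose episode target is 0 minutes nevertheless carries a short
#'   (5 to 9 minute) episode, so zero-target cohorts still show a realistic
#'   upper quartile.
#' @param accel_amplitude_range,accel_duration_range_s Planted acceleration
#'   amplitude (bpm above baseline) and duration (s); the lower amplitude
#'   bound keeps planted events above the 10-bpm detection threshold by a
#'   margin larger than the variability excursion.
#' @param decel_depth_range Planted deceleration depth range (bpm below
#'   baseline); depths stay above the 20-bpm criterion with margin.
#' @param dbd_max Maximum days-before-delivery for APO traces.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_npo = 500, n_apo = 500,
                       gestation_range = c(189, 258),
                       duration_minutes_range = c(35, 75),
                       sampling_rate = 4,
                       seed = 1,
                       cohort_feature_targets = default_feature_targets(),
                       signal_loss_fraction_range = c(0.02, 0.12),
                       subtype_prevalences = default_subtype_prevalences(),
                       subtype_correlation = 0.3,
                       p_male = 4335 / 8881,
                       extra_high_episode_prob = 0.4,
                       extra_low_episode_prob = 0.3,
                       accel_amplitude_range = c(19, 28),
                       accel_duration_range_s = c(28, 45),
                       decel_depth_range = c(23, 32),
                       dbd_max = 7) {
  cfg <- as.list(environment())
  # tolerate list-shaped inputs (e.g. a YAML round-trip)
  cfg$subtype_prevalences <- unlist(cfg$subtype_prevalences)
  for (nm in c("gestation_range", "duration_minutes_range",
               "signal_loss_fraction_range", "accel_amplitude_range",
               "accel_duration_range_s", "decel_depth_range")) {
    cfg[[nm]] <- as.numeric(unlist(cfg[[nm]]))
  }
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  if (cfg$n_npo < 0 || cfg$n_apo < 0) {
    stop("invalid-config: cohort sizes must be non-negative")
  }
  if (cfg$sampling_rate <= 0) {
    stop("invalid-config: sampling_rate must be positive")
  }
  if (any(!is.finite(cfg$duration_minutes_range)) ||
      any(cfg$duration_minutes_range <= 0)) {
    stop("invalid-config: duration range must be positive")
  }
  if (cfg$gestation_range[1] < 189 || cfg$gestation_range[2] > 258 ||
      cfg$gestation_range[1] > cfg$gestation_range[2]) {
    stop("invalid-config: gestation bounds must lie within [189, 258] days")
  }
  if (any(cfg$subtype_prevalences < 0 | cfg$subtype_prevalences > 1)) {
    stop("invalid-config: subtype prevalences must lie in [0, 1]")
  }
  for (coh in c("NPO", "APO")) {
    tg <- cfg$cohort_feature_targets[[coh]]
    if (is.null(tg)) stop("invalid-config: missing targets for cohort ", coh)
    if (any(unlist(tg) < 0)) {
      stop("invalid-config: infeasible (negative) feature target for ", coh)
    }
    if (tg$basal_fhr < 100 || tg$basal_fhr > 180) {
      stop("invalid-config: basal target outside [100, 180] bpm for ", coh)
    }
  }
  invisible(cfg)
}

#' @keywords internal
pi_ms <- function(bpm) 60000 / bpm

#' @keywords internal
#' Tukey (tapered cosine) window of n samples.
tukey_window <- function(n, alpha = 0.4) {
  if (n <= 2) return(rep(1, n))
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / alpha - 2 / alpha + 1)))
  w
}

#' @keywords internal
#' Pick non-overlapping episode blocks (in whole minutes, 1-based) inside
#' [first, last], keeping `buffer` minutes clear of `occupied` minutes.
place_block <- function(len, first, last, occupied, buffer = 2) {
  if (len <= 0) return(integer())
  starts <- first:max(first, last - len + 1)
  ok <- vapply(starts, function(s) {
    mins <- (s - buffer):(s + len - 1 + buffer)
    s + len - 1 <= last && !any(mins %in% occupied)
  }, logical(1))
  if (!any(ok)) return(integer())
  s <- sample_safe(starts[ok], 1)
  s:(s + len - 1)
}

#' Simulate one FHR trace with planted ground truth
#'
#' @param config A [sim_config()].
#' @param cohort `"NPO"` or `"APO"`.
#' @param seed Integer seed; identical `(config, cohort, seed)` yields an
#'   identical trace.
#' @param trace_id Identifier for the trace.
#' @param metadata Extra metadata to attach (gestational age etc.).
#' @return List with elements `trace` (an [fhr_trace()]) and `truth`, the
#'   planted ground truth: event table (onset, offset, amplitude), true
#'   baseline trajectory, planted high/low-variation minute indices, missing
#'   intervals and the per-trace targets actually planted.
#' @export
simulate_trace <- function(config, cohort = c("NPO", "APO"), seed = 1,
                           trace_id = sprintf("%s_%06d", cohort[1], seed),
                           metadata = list()) {
  cohort <- match.arg(cohort)
  validate_sim_config(config)
  set.seed(seed)
  tg <- config$cohort_feature_targets[[cohort]]
  rate <- config$sampling_rate
  noise_on <- tg$stv > 0

  dur_min <- stats::runif(1, config$duration_minutes_range[1],
                          config$duration_minutes_range[2])
  if (!noise_on) dur_min <- round(dur_min)
  n <- as.integer(round(dur_min * 60 * rate))
  time_s <- (seq_len(n) - 1L) / rate
  analysed_min <- as.integer(floor(min(60, dur_min)))
  n_min_total <- as.integer(ceiling(dur_min))

  # --- baseline trajectory: level + slow drift + a few small steps --------
  if (noise_on) {
    b0 <- max(115, min(172, stats::rnorm(1, tg$basal_fhr, 3.5)))
    drift <- stats::runif(1, -3, 3)
    b <- b0 + drift * (time_s / max(time_s) - 0.5)
    n_steps <- sample(0:3, 1)
    if (n_steps > 0) {
      cp <- sort(sample.int(n - 1, n_steps))
      offs <- stats::rnorm(n_steps, 0, 1.5)
      step_sig <- numeric(n)
      for (k in seq_len(n_steps)) step_sig[(cp[k] + 1):n] <- step_sig[(cp[k] + 1):n] + offs[k]
      b <- b + step_sig - mean(step_sig)
    }
    b <- pmax(100.5, pmin(179.5, b))
  } else {
    b <- rep(tg$basal_fhr, n)
  }

  # --- minute states: planted high/low variation episodes -----------------
  states <- rep("M", n_min_total)
  draw_block_len <- function(target, extra_p) {
    if (target > 0) {
      max(5, round(target * exp(stats::rnorm(1, 0, 0.45))))
    } else if (stats::runif(1) < extra_p) {
      sample(5:9, 1)
    } else 0L
  }
  span_first <- 2L
  span_last <- max(span_first, analysed_min - 1L)
  high_len <- if (noise_on) min(draw_block_len(tg$high_variation_min,
                                               config$extra_high_episode_prob),
                                max(0, span_last - span_first - 3)) else 0L
  occupied <- integer()
  high_mins <- place_block(high_len, span_first, span_last, occupied)
  occupied <- c(occupied, high_mins)
  low_len <- if (noise_on) min(draw_block_len(tg$low_variation_min,
                                              config$extra_low_episode_prob),
                               max(0, span_last - span_first - 3)) else 0L
  low_mins <- place_block(low_len, span_first, span_last, occupied)
  occupied <- c(occupied, low_mins)
  states[high_mins] <- "H"
  states[low_mins] <- "L"

  # --- events: counts from targets, lost beats from the MLB target --------
  # Events may span their slot minute and the next; keep them >= 2 clear
  # minutes from planted episode blocks and >= 3 minutes apart so stray
  # qualifying minutes can never reach the 5-of-6 episode persistence rule.
  ev_last <- max(span_first, analysed_min - 2L)
  free_mins <- setdiff(seq(span_first, ev_last),
                       c(outer(occupied, -3:2, "+")))
  n_acc <- if (tg$accelerations > 0) stats::rpois(1, tg$accelerations + 0.2) else 0L
  n_dec <- if (tg$decelerations > 0) stats::rpois(1, tg$decelerations + 0.2) else 0L
  ev_slots <- integer()
  pick_slot <- function(free, taken) {
    cand <- if (length(taken)) setdiff(free, c(outer(taken, -2:2, "+"))) else free
    if (!length(cand)) return(NA_integer_)
    sample_safe(cand, 1)
  }
  events <- list()
  if (n_dec > 0) {
    lb_base <- tg$most_lost_beats * exp(stats::rnorm(1, 0, 0.28))
    for (k in seq_len(n_dec)) {
      slot <- pick_slot(free_mins, ev_slots)
      if (is.na(slot)) break
      ev_slots <- c(ev_slots, slot)
      lb <- max(12.6, lb_base * exp(stats::rnorm(1, 0, 0.12)))
      # ~0.6 beats of the extracted area come from adjacent variability dips
      lb_plant <- max(12, lb - 0.6)
      depth <- stats::runif(1, config$decel_depth_range[1], config$decel_depth_range[2])
      lb_plant <- min(lb_plant, depth * 115 / 60)  # keep events within two minutes
      dur_s <- 60 * lb_plant / depth
      if (dur_s < 32.5) {
        dur_s <- 32.5
        depth <- 60 * lb_plant / dur_s  # >= 22.2 bpm: clear of the 20-bpm criterion
      }
      onset <- (slot - 1) * 60 + stats::runif(1, 0, max(0.5, min(60, 118 - dur_s)))
      events[[length(events) + 1L]] <- data.frame(
        kind = "deceleration", onset_s = onset, dur_s = dur_s,
        amplitude_bpm = -depth, planted_lost_beats = depth * dur_s / 60)
    }
  }
  if (n_acc > 0) {
    for (k in seq_len(n_acc)) {
      slot <- pick_slot(free_mins, ev_slots)
      if (is.na(slot)) break
      ev_slots <- c(ev_slots, slot)
      amp <- stats::runif(1, config$accel_amplitude_range[1],
                          config$accel_amplitude_range[2])
      dur_s <- stats::runif(1, config$accel_duration_range_s[1],
                            config$accel_duration_range_s[2])
      onset <- (slot - 1) * 60 + stats::runif(1, 0, max(0.5, min(60, 118 - dur_s)))
      events[[length(events) + 1L]] <- data.frame(
        kind = "acceleration", onset_s = onset, dur_s = dur_s,
        amplitude_bpm = amp, planted_lost_beats = NA_real_)
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(kind = character(), onset_s = numeric(), dur_s = numeric(),
               amplitude_bpm = numeric(), planted_lost_beats = numeric())
  if (nrow(events)) events <- events[order(events$onset_s), , drop = FALSE]

  # --- variability: per-minute pinned epoch pulse-interval ranges ---------
  ep_len <- as.integer(round(3.75 * rate))
  eppm <- as.integer(round(60 / 3.75))    # epochs per minute
  n_ep <- n %/% ep_len
  pi_dev_ep <- numeric(max(n_ep, 0))
  stv_target <- tg$stv * exp(stats::rnorm(1, 0, 0.18))
  if (noise_on && n_ep >= 2) {
    F_m <- vapply(states, function(s) switch(s,
      H = stats::runif(1, 36, 56),
      L = stats::runif(1, 14, 26),
      M = stats::runif(1, 30.4, 31.6)), numeric(1))
    # event contribution to the sum of |epoch differences| (accelerations
    # only: deceleration epochs are excluded from STV downstream)
    em <- 0
    if (nrow(events)) {
      acc <- events[events$kind == "acceleration", , drop = FALSE]
      if (nrow(acc)) {
        em <- sum(2 * abs(pi_ms(tg$basal_fhr + acc$amplitude_bpm) -
                            pi_ms(tg$basal_fhr)))
      }
    }
    n_diffs <- max(1, analysed_min * eppm - 1)
    adj_target <- max(0.4, (stv_target * n_diffs - em) / n_diffs)
    # 0.955: measured attenuation of the closed-form sinusoid prediction due
    # to per-minute rescaling and minute-boundary discontinuities
    rbar <- mean(F_m[seq_len(analysed_min)]) * 0.955
    s_arg <- max(0.05, min(0.95, adj_target * pi / (2 * rbar)))
    cyc <- (16 / pi) * asin(s_arg)     # behavioural-cycling rate, cycles/min
    phase0 <- stats::runif(1, 0, 2 * pi)
    ph <- phase0 + 2 * pi * cyc * (seq_len(n_ep) - 1L) * 3.75 / 60
    jit <- as.numeric(stats::filter(stats::rnorm(n_ep, 0, 0.08), 0.6,
                                    method = "recursive"))
    raw <- sin(ph) + jit
    for (m in seq_len(n_min_total)) {
      idx <- ((m - 1L) * eppm + 1L):min(m * eppm, n_ep)
      if (length(idx) < 2 || idx[1] > n_ep) next
      v <- raw[idx]
      rng <- max(v) - min(v)
      if (rng <= 0) next
      v <- (v - min(v)) / rng * F_m[m]
      pi_dev_ep[idx] <- v - mean(v)
    }
  }
  pi_dev <- if (n_ep > 0) rep(pi_dev_ep, each = ep_len)[seq_len(min(n, n_ep * ep_len))] else numeric(0)
  if (length(pi_dev) < n) pi_dev <- c(pi_dev, rep(utils::tail(c(0, pi_dev), 1), n - length(pi_dev)))

  # --- assemble signal -----------------------------------------------------
  e_bpm <- numeric(n)
  mute <- rep(1, n)
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      i1 <- max(1L, as.integer(floor(events$onset_s[i] * rate)) + 1L)
      i2 <- min(n, as.integer(ceiling((events$onset_s[i] + events$dur_s[i]) * rate)))
      if (i2 < i1) next
      if (events$kind[i] == "acceleration") {
        w <- tukey_window(i2 - i1 + 1L, alpha = 0.4)
        e_bpm[i1:i2] <- e_bpm[i1:i2] + events$amplitude_bpm[i] * w
      } else {
        e_bpm[i1:i2] <- e_bpm[i1:i2] + events$amplitude_bpm[i]
        mute[i1:i2] <- 0.1
      }
    }
  }
  fhr <- 60000 / (pi_ms(b + e_bpm) + pi_dev * mute)

  # --- signal loss ---------------------------------------------------------
  mask <- rep(FALSE, n)
  miss_intervals <- NULL
  loss_frac <- stats::runif(1, config$signal_loss_fraction_range[1],
                            config$signal_loss_fraction_range[2])
  n_miss <- round(loss_frac * n)
  if (n_miss > 0) {
    gap_mins <- setdiff(free_mins, c(ev_slots, ev_slots + 1L))
    pool <- unlist(lapply(gap_mins, function(m) {
      ((m - 1L) * 60L * rate + 1L):min(n, m * 60L * rate)
    }))
    pool <- sort(pool)
    n_miss <- min(n_miss, length(pool))
    if (n_miss > 0) {
      k_gaps <- min(1L + stats::rpois(1, 2), n_miss)
      sizes <- as.vector(stats::rmultinom(1, n_miss - k_gaps, rep(1, k_gaps))) + 1L
      taken <- logical(length(pool))
      for (g in seq_len(k_gaps)) {
        avail <- which(!taken)
        if (!length(avail)) break
        start <- sample_safe(avail, 1)
        span <- start:min(start + sizes[g] - 1L, length(pool))
        taken[span] <- TRUE
      }
      sel <- pool[taken]
      deficit <- n_miss - length(sel)
      if (deficit > 0) {
        extra <- setdiff(pool, sel)
        sel <- c(sel, utils::head(extra, deficit))
      }
      mask[sel] <- TRUE
      runs <- logical_runs(mask)
      miss_intervals <- data.frame(onset_s = time_s[runs[, 1]],
                                   offset_s = time_s[runs[, 2]] + 1 / rate)
    }
  }
  fhr[mask] <- NA_real_

  trace <- fhr_trace(trace_id, time_s, fhr, mask, sampling_rate = rate,
                     metadata = metadata)
  truth <- list(
    events = data.frame(kind = events$kind,
                        onset_s = events$onset_s,
                        offset_s = events$onset_s + events$dur_s,
                        amplitude_bpm = events$amplitude_bpm,
                        planted_lost_beats = events$planted_lost_beats),
    baseline_bpm = b,
    high_variation_minutes = high_mins,
    low_variation_minutes = low_mins,
    missing_intervals = miss_intervals,
    stv_target_ms = stv_target,
    signal_loss_fraction = sum(mask) / n,
    duration_min = dur_min
  )
  list(trace = trace, truth = truth)
}

#' @keywords internal
#' Exact-count shuffled allocation of fetal sex.
allocate_sex <- function(n, p_male) {
  n_male <- round(n * p_male)
  sample(c(rep("male", n_male), rep("female", n - n_male)))
}

#' @keywords internal
#' Correlated subtype labels via a Gaussian copula; every row gets >= 1 label.
draw_subtypes <- function(n, prev, rho) {
  k <- length(prev)
  z0 <- stats::rnorm(n)
  lab <- matrix(0L, n, k, dimnames = list(NULL, names(prev)))
  thr <- stats::qnorm(prev)
  score <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    z <- sqrt(rho) * z0 + sqrt(1 - rho) * stats::rnorm(n)
    lab[, j] <- as.integer(z < thr[j])
    score[, j] <- thr[j] - z
  }
  none <- rowSums(lab) == 0L
  if (any(none)) {
    forced <- max.col(score[none, , drop = FALSE])
    lab[cbind(which(none), forced)] <- 1L
  }
  lab
}

#' Simulate cohort covariates and outcome labels (no signals)
#'
#' Generates the per-trace covariate and label table that [simulate_cohort()]
#' attaches to its traces: gestational age, fetal sex, trace duration,
#' days before delivery (APO), and ten adverse-outcome subtype labels.
#' Gestational ages overlap between cohorts (APO mildly skewed later, as
#' traces are acquired within a week of a preterm delivery) so that
#' propensity matching is feasible.
#'
#' @param config A [sim_config()].
#' @return Data frame of cohort records (see [read_cohort_table()] for the
#'   schema) with additional `pregnancy_id` and `acquisition_order` columns.
#' @export
simulate_covariates <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_npo + config$n_apo
  cohort <- c(rep("NPO", config$n_npo), rep("APO", config$n_apo))
  g1 <- config$gestation_range[1]
  g2 <- config$gestation_range[2]
  ga <- numeric(n)
  ga[cohort == "NPO"] <- floor(stats::runif(config$n_npo, g1, g2 + 1))
  ga[cohort == "APO"] <- floor(g1 + (g2 - g1 + 1) *
                                 stats::rbeta(config$n_apo, 1.3, 1.0))
  ga <- pmin(ga, g2)
  sex <- character(n)
  sex[cohort == "NPO"] <- allocate_sex(config$n_npo, config$p_male)
  sex[cohort == "APO"] <- allocate_sex(config$n_apo, config$p_male)
  dur <- stats::runif(n, config$duration_minutes_range[1],
                      config$duration_minutes_range[2])
  dbd <- rep(NA_real_, n)
  dbd[cohort == "APO"] <- sample(0:config$dbd_max, config$n_apo, replace = TRUE)
  rec <- data.frame(
    trace_id = sprintf("%s_%06d", cohort, seq_len(n)),
    pregnancy_id = sprintf("P%06d", seq_len(n)),
    cohort = cohort,
    gestational_age_days = ga,
    fetal_sex = sex,
    duration_min = dur,
    days_before_delivery = dbd,
    acquisition_order = 1L,
    stringsAsFactors = FALSE
  )
  sub <- matrix(0L, n, length(config$subtype_prevalences),
                dimnames = list(NULL, paste0("subtype_", names(config$subtype_prevalences))))
  if (config$n_apo > 0) {
    sub[cohort == "APO", ] <- draw_subtypes(config$n_apo,
                                            config$subtype_prevalences,
                                            config$subtype_correlation)
  }
  cbind(rec, as.data.frame(sub))
}

#' Simulate a full cohort of FHR traces
#'
#' @param config A [sim_config()].
#' @param progress Unused placeholder for a progress callback.
#' @return List with `traces` (list of [fhr_trace()]), `records` (cohort
#'   table; the `duration_min` column holds each trace's realised duration)
#'   and `truths` (per-trace planted ground truth).
#' @export
simulate_cohort <- function(config, progress = NULL) {
  records <- simulate_covariates(config)
  n <- nrow(records)
  traces <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    md <- list(gestational_age_days = records$gestational_age_days[i],
               fetal_sex = records$fetal_sex[i],
               days_before_delivery = records$days_before_delivery[i],
               pregnancy_id = records$pregnancy_id[i],
               cohort = records$cohort[i])
    st <- simulate_trace(config, records$cohort[i], seed = config$seed + i,
                         trace_id = records$trace_id[i], metadata = md)
    traces[[i]] <- st$trace
    truths[[i]] <- st$truth
    records$duration_min[i] <- st$truth$duration_min
  }
  list(traces = traces, records = records, truths = truths)
}

#' Export traces and a cohort table as CSV fixtures
#'
#' Writes one trace CSV per trace plus `cohort.csv`, all round-trippable by
#' [read_trace()] / [read_cohort_table()].
#'
#' @param traces List of [fhr_trace()] objects.
#' @param records Cohort record data frame aligned with `traces`.
#' @param path Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_fixture <- function(traces, records, path) {
  if (length(traces) != nrow(records)) {
    stop("validation error: traces and records are not aligned")
  }
  validate_cohort_table(records, "<records>")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("I/O error: cannot create directory ", path)
  paths <- character(0)
  for (i in seq_along(traces)) {
    p <- file.path(path, paste0(traces[[i]]$trace_id, ".csv"))
    write_trace(traces[[i]], p)
    paths <- c(paths, p)
  }
  ct <- file.path(path, "cohort.csv")
  write_cohort_table(records, ct)
  invisible(c(paths, ct))
}
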