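# Feature extraction: baseline, events, lost beats, STV, variation episodes.

test_that("baseline is the signal itself on a constant trace and ignores transients", {
  tr <- flat_trace(140, minutes = 20)
  expect_equal(fit_baseline(tr), rep(140, length(tr$fhr_bpm)))

  # +15 bpm for 20 s: baseline must stay within 140 +/- 2 everywhere
  tr2 <- with_plateau(flat_trace(140, 20), dev = 15, onset_s = 600, dur_s = 20)
  b2 <- fit_baseline(tr2)
  expect_true(all(abs(b2 - 140) < 2))

  # 60-s, -30 bpm deceleration moves the baseline by < 2 bpm at any sample
  tr3 <- with_plateau(flat_trace(140, 20), dev = -30, onset_s = 500, dur_s = 60)
  b3 <- fit_baseline(tr3)
  expect_true(all(abs(b3 - 140) < 2))
})

test_that("baseline matches a brute-force trimmed moving mean and tracks drift", {
  # independent oracle: windowed mean excluding samples > 10 bpm from the
  # global trimmed level, computed sample-by-sample
  tr <- with_plateau(flat_trace(140, 15), dev = 15, onset_s = 300, dur_s = 20)
  b <- fit_baseline(tr)
  x <- tr$fhr_bpm
  half <- 10 * 60 * 4 / 2
  oracle <- vapply(seq_along(x), function(i) {
    w <- x[max(1, i - half):min(length(x), i + half)]
    mean(w[abs(w - 140) <= 10])
  }, numeric(1))
  expect_lt(max(abs(b - oracle)), 0.5)

  n <- 30 * 60 * 4
  drift <- fhr_trace("drift", (seq_len(n) - 1) / 4,
                     seq(130, 150, length.out = n))
  bd <- fit_baseline(drift)
  expect_true(all(abs(bd - drift$fhr_bpm) < 3))
})

test_that("event detection enforces the printed amplitude-duration criteria", {
  base <- flat_trace(140, 20)
  b <- rep(140, length(base$fhr_bpm))

  # +12 bpm for 10 s: too short for an acceleration
  ev <- detect_events(with_plateau(base, 12, 600, 10), b)
  expect_equal(nrow(ev), 0)

  # +12 bpm for 20 s: one acceleration
  ev <- detect_events(with_plateau(base, 12, 600, 20), b)
  expect_equal(ev$kind, "acceleration")

  # -25 bpm for 40 s: exactly one deceleration (deep criterion)
  ev <- detect_events(with_plateau(base, -25, 600, 40), b)
  expect_equal(ev$kind, "deceleration")
  expect_equal(nrow(ev), 1)

  # -12 bpm for 45 s: fails both deceleration criteria
  ev <- detect_events(with_plateau(base, -12, 600, 45), b)
  expect_equal(nrow(ev), 0)

  # -12 bpm for 65 s: qualifies via the shallow-long criterion
  ev <- detect_events(with_plateau(base, -12, 600, 65), b)
  expect_equal(ev$kind, "deceleration")

  # -30 bpm for 60 s: planted example must be detected
  ev <- detect_events(with_plateau(base, -30, 600, 60), b)
  expect_equal(ev$kind, "deceleration")
})

test_that("sub-threshold gaps shorter than 5 s are bridged", {
  base <- flat_trace(140, 20)
  b <- rep(140, length(base$fhr_bpm))
  # two 10-s accel plateaus separated by a 3-s dip: one merged acceleration
  tr <- with_plateau(with_plateau(base, 15, 600, 10), 15, 613, 10)
  ev <- detect_events(tr, b)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "acceleration")
  # separated by 8 s: two runs, each too short to qualify
  tr2 <- with_plateau(with_plateau(base, 15, 600, 10), 15, 618, 10)
  expect_equal(nrow(detect_events(tr2, b)), 0)
})

test_that("lost beats equal depth x duration for rectangles and area for triangles", {
  base <- flat_trace(140, 20)
  b <- rep(140, length(base$fhr_bpm))

  tr <- with_plateau(base, -30, 600, 60)
  ev <- detect_events(tr, b)
  expect_equal(ev$lost_beats, 30, tolerance = 0.01)

  tr <- with_plateau(base, -10, 600, 120)
  ev <- detect_events(tr, b)
  expect_equal(ev$lost_beats, 20, tolerance = 0.01)

  # triangular dip peaking at -20 over 60 s: area = 0.5 * 20 * 1 = 10 beats
  tr <- with_plateau(base, -20, 600, 60, shape = "triangle")
  event <- data.frame(kind = "deceleration", onset_s = 615, offset_s = 645)
  expect_equal(lost_beats(event, tr, b), 10, tolerance = 0.02)

  acc <- data.frame(kind = "acceleration", onset_s = 0, offset_s = 10)
  expect_error(lost_beats(acc, tr, b), "contract violation")
})

test_that("most lost beats is the maximum over decelerations, zero without any", {
  expect_equal(most_lost_beats(data.frame(kind = character(),
                                          lost_beats = numeric())), 0)
  ev <- data.frame(kind = rep("deceleration", 3), lost_beats = c(12, 30, 7))
  expect_equal(most_lost_beats(ev), 30)
  expect_equal(most_lost_beats(ev[2, ]), 30)
  # accelerations are ignored
  ev2 <- rbind(ev, data.frame(kind = "acceleration", lost_beats = NA))
  expect_equal(most_lost_beats(ev2), 30)
})

test_that("STV matches the closed form for alternating epochs and is 0 when flat", {
  expect_equal(compute_stv(flat_trace(140, 10)), 0)

  # epochs alternating 140/150 bpm: STV = |60000/140 - 60000/150|
  n_ep <- 40
  fhr <- rep(rep(c(140, 150), length.out = n_ep), each = 15)
  tr <- fhr_trace("alt", (seq_along(fhr) - 1) / 4, fhr)
  expect_equal(compute_stv(tr), 60000 / 140 - 60000 / 150, tolerance = 1e-12)
})

test_that("STV converges to the planted mean absolute successive difference", {
  # epoch-constant pulse-interval noise with known E|diff|
  set.seed(9)
  n_ep <- 16 * 60  # one hour of epochs
  pi0 <- 60000 / 140
  sigma <- 6
  ep_pi <- pi0 + rnorm(n_ep, 0, sigma)
  expected <- 2 * sigma / sqrt(pi)  # E|X-Y|, X,Y ~ N(0, sigma^2)
  fhr <- rep(60000 / ep_pi, each = 15)
  tr <- fhr_trace("mc", (seq_along(fhr) - 1) / 4, fhr)
  expect_equal(compute_stv(tr), expected, tolerance = 0.05)
})

test_that("STV excludes epochs overlapping detected decelerations", {
  base <- flat_trace(140, 20)
  tr <- with_plateau(base, -30, 300, 60)
  b <- rep(140, length(tr$fhr_bpm))
  ev <- detect_events(tr, b)
  # with the deceleration masked the trace is flat: STV 0
  expect_equal(compute_stv(tr, ev), 0)
  # without masking the deceleration edges leak into the differences
  expect_gt(compute_stv(tr, NULL), 0)
})

test_that("variation episodes follow the 5-of-6 persistence rule", {
  # constant trace: zero variability => all minutes low, none high
  tr <- flat_trace(140, 30)
  ve <- variation_episodes(tr)
  expect_equal(unname(ve["high_variation_min"]), 0)
  expect_equal(unname(ve["low_variation_min"]), 30)

  # 10 consecutive minutes with epoch PI range ~50 ms, rest flat
  mk_high <- function(high_minutes, total_min = 30) {
    n_ep <- total_min * 16
    ep_dev <- numeric(n_ep)
    for (m in high_minutes) {
      idx <- ((m - 1) * 16 + 1):(m * 16)
      ep_dev[idx] <- rep(c(-25, 25), length.out = 16)
    }
    pi0 <- 60000 / 140
    fhr <- rep(60000 / (pi0 + ep_dev), each = 15)
    fhr_trace("h", (seq_along(fhr) - 1) / 4, fhr)
  }
  ve <- variation_episodes(mk_high(6:15))
  expect_equal(unname(ve["high_variation_min"]), 10)

  # only 3 qualifying minutes: below the persistence rule
  ve <- variation_episodes(mk_high(6:8))
  expect_equal(unname(ve["high_variation_min"]), 0)
})

test_that("episode marking agrees with a brute-force window scanner", {
  set.seed(11)
  params <- feature_params()
  for (rep_i in 1:50) {
    q <- runif(40) < 0.4
    # build a trace whose minutes qualify as high exactly where q is TRUE
    n_min <- length(q)
    ep_dev <- numeric(n_min * 16)
    for (m in which(q)) {
      idx <- ((m - 1) * 16 + 1):(m * 16)
      ep_dev[idx] <- rep(c(-25, 25), length.out = 16)
    }
    pi0 <- 60000 / 140
    fhr <- rep(60000 / (pi0 + ep_dev), each = 15)
    tr <- fhr_trace("q", (seq_along(fhr) - 1) / 4, fhr)
    ve <- variation_episodes(tr)
    expect_equal(unname(ve["high_variation_min"]),
                 oracle_mark_episode_minutes(q), info = paste("rep", rep_i))
  }
})

test_that("extract_features matches the degenerate closed-form trace", {
  fv <- extract_features(flat_trace(140, 30))
  expect_equal(fv$basal_fhr, 140)
  expect_equal(fv$accelerations, 0)
  expect_equal(fv$decelerations, 0)
  expect_equal(fv$most_lost_beats, 0)
  expect_equal(fv$stv, 0)
  expect_equal(fv$high_variation_min, 0)
  expect_equal(fv$low_variation_min, 30)
  expect_equal(fv$analysed_duration_min, 30)
  expect_equal(fv$signal_loss_pct, 0)
})

test_that("features are not extracted beyond 60 minutes", {
  tr <- with_plateau(flat_trace(140, 90), dev = -30, onset_s = 70 * 60,
                     dur_s = 60)
  fv <- extract_features(tr)
  expect_equal(fv$decelerations, 0)
  expect_equal(fv$analysed_duration_min, 60)
  # same event inside the window is counted
  tr2 <- with_plateau(flat_trace(140, 90), dev = -30, onset_s = 30 * 60,
                      dur_s = 60)
  expect_equal(extract_features(tr2)$decelerations, 1)
})

test_that("features are invariant to time translation", {
  cfg <- sim_config()
  st <- simulate_trace(cfg, "NPO", seed = 21)
  fv1 <- extract_features(st$trace)
  shifted <- st$trace
  shifted$time_s <- shifted$time_s + 1234.5
  fv2 <- extract_features(shifted)
  expect_equal(fv1[, -1], fv2[, -1])
})

test_that("adding c bpm shifts the basal rate by c and preserves counts", {
  cfg <- sim_config()
  st <- simulate_trace(cfg, "APO", seed = 33)
  fv1 <- extract_features(st$trace)
  up <- st$trace
  up$fhr_bpm <- up$fhr_bpm + 10
  fv2 <- extract_features(up)
  expect_equal(fv2$basal_fhr, fv1$basal_fhr + 10, tolerance = 1e-6)
  expect_equal(fv2$accelerations, fv1$accelerations)
  expect_equal(fv2$decelerations, fv1$decelerations)
  expect_equal(fv2$most_lost_beats, fv1$most_lost_beats, tolerance = 1e-6)
  # STV lives on the pulse-interval scale: a +c bpm shift rescales it by
  # roughly (b / (b + c))^2; check the rescaled agreement
  ratio <- (fv1$basal_fhr / fv2$basal_fhr)^2
  expect_equal(fv2$stv, fv1$stv * ratio, tolerance = 0.05)
})

test_that("deepening a planted deceleration never decreases most lost beats", {
  base <- flat_trace(140, 20)
  depths <- c(-22, -26, -30, -35)
  mlb <- vapply(depths, function(d) {
    extract_features(with_plateau(base, d, 600, 45))$most_lost_beats
  }, numeric(1))
  expect_true(all(diff(mlb) > 0))
})

test_that("degenerate inputs raise extraction errors", {
  n <- 4 * 60 * 5
  all_miss <- fhr_trace("m", (seq_len(n) - 1) / 4, rep(NA_real_, n),
                        missing_mask = rep(TRUE, n))
  expect_error(extract_features(all_miss), "entirely missing")

  short <- fhr_trace("s", (0:30) / 4, rep(140, 31))
  expect_error(fit_baseline(short), "non-missing minute")
})
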