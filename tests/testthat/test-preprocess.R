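# Cleaning and QC chain: blink interpolation, smoothing, z-transform,
# missingness and gaze rejection.

mk_series <- function(pupil, valid = rep(TRUE, length(pupil)), fs = 250,
                      gx = 512, gy = 384) {
  s <- data.frame(participant_id = "P1",
                  time_s = (seq_along(pupil) - 1) / fs,
                  pupil = ifelse(valid, pupil, NA_real_),
                  gaze_x_px = gx, gaze_y_px = gy, valid = valid)
  attr(s, "sampling_rate_hz") <- fs
  s
}

test_that("blink interpolation draws straight lines between pad anchors", {
  # zero padding: anchors are the adjacent valid samples
  s <- mk_series(c(1, 2, 0, 0, 5), valid = c(TRUE, TRUE, FALSE, FALSE, TRUE))
  out <- interpolate_blinks(s, pad_ms = 0)
  expect_equal(out$pupil, c(1, 2, 3, 4, 5))
  expect_identical(out$interpolated, c(FALSE, FALSE, TRUE, TRUE, FALSE))

  # no invalid samples: identity, nothing marked interpolated
  s2 <- mk_series(sin(1:100))
  out2 <- interpolate_blinks(s2, pad_ms = 100)
  expect_equal(out2$pupil, s2$pupil)
  expect_false(any(out2$interpolated))

  # 50-sample interior blink, 100 ms pad at 250 Hz: anchors sit 25 samples
  # outside the run; every replaced value lies on the two-anchor line
  set.seed(8)
  pupil <- cumsum(rnorm(500))
  valid <- rep(TRUE, 500)
  valid[201:250] <- FALSE
  s3 <- mk_series(pupil, valid)
  out3 <- interpolate_blinks(s3, pad_ms = 100)
  a <- 201 - 25  # last valid sample exactly 100 ms before the run start
  b <- 250 + 25  # first valid sample exactly 100 ms after the run end
  expect_equal(out3$pupil[a], pupil[a])
  expect_equal(out3$pupil[b], pupil[b])
  fill <- (a + 1):(b - 1)
  expect_equal(out3$pupil[fill],
               oracle_line(s3$time_s[a], pupil[a], s3$time_s[b], pupil[b],
                           s3$time_s[fill]))
  expect_true(all(out3$interpolated[fill]))
  # valid samples outside the padded region are untouched
  expect_equal(out3$pupil[-fill], pupil[-fill])

  # a blink touching the session start stays missing
  v4 <- rep(TRUE, 100); v4[1:10] <- FALSE
  out4 <- interpolate_blinks(mk_series(rnorm(100), v4), pad_ms = 100)
  expect_true(all(is.na(out4$pupil[1:10])))

  expect_error(interpolate_blinks(mk_series(rep(1, 5), valid = rep(FALSE, 5))),
               "entire series")
})

test_that("sliding-mean smoothing averages a truncated centred window", {
  s <- mk_series(rep(3.7, 200))
  expect_equal(smooth_sliding_mean(s)$pupil, rep(3.7, 200))

  # impulse at 250 Hz with a 200 ms window: interior value is 1/51
  x <- rep(0, 300); x[150] <- 1
  sm <- smooth_sliding_mean(mk_series(x), window_ms = 200)
  expect_equal(sm$pupil[150], 1 / 51)
  expect_equal(sm$pupil[150 - 25], 1 / 51)
  expect_equal(sm$pupil[150 - 26], 0)
  # edge truncation: shorter windows near the boundary
  x2 <- rep(0, 100); x2[1] <- 1
  sm2 <- smooth_sliding_mean(mk_series(x2), window_ms = 200)
  expect_equal(sm2$pupil[1], 1 / 26)

  # a window shorter than one sample period changes nothing
  s3 <- mk_series(rnorm(50))
  expect_equal(smooth_sliding_mean(s3, window_ms = 3)$pupil, s3$pupil)

  # gaze and validity are untouched
  v <- rep(TRUE, 50); v[10] <- FALSE
  s4 <- mk_series(rnorm(50), v)
  expect_identical(smooth_sliding_mean(s4)$valid, v)
})

test_that("session z-transform standardizes usable samples", {
  s <- mk_series(c(0, 2))
  z <- zscore_session(s)
  expect_equal(z$pupil, c(-1, 1) / sqrt(2))

  set.seed(9)
  s2 <- mk_series(rnorm(400, 5, 2.3), valid = c(rep(TRUE, 380), rep(FALSE, 20)))
  z2 <- zscore_session(s2)
  ok <- !is.na(z2$pupil)
  expect_equal(mean(z2$pupil[ok]), 0, tolerance = 1e-10)
  expect_equal(sd(z2$pupil[ok]), 1, tolerance = 1e-10)
  # idempotence up to float tolerance
  z3 <- zscore_session(z2)
  expect_equal(z3$pupil, z2$pupil, tolerance = 1e-10)

  expect_error(zscore_session(mk_series(rep(2, 10))), "zero variance")
})

test_that("missingness rejection applies strict thresholds", {
  fs <- 250
  n_win <- 6 * fs
  ev <- data.frame(participant_id = "P1", trial_index = 1:2,
                   condition = c("reward", "control"),
                   fixation_onset_s = c(1, 9), cue_onset_s = c(2, 10),
                   cue_offset_s = c(8, 16), feedback_onset_s = c(8.5, NA),
                   feedback_success = c(TRUE, NA))
  # trial 1: exactly 50% of its window missing -> kept (strict >)
  v <- rep(TRUE, 17 * fs)
  v[window_idx_test((seq_along(v) - 1) / fs, 2, 5)] <- FALSE
  s <- mk_series(rnorm(17 * fs), v)
  qc <- reject_missing(s, ev, preprocess_params(pad_ms = 0))
  expect_equal(qc$trials$trial_missing_fraction[1], 0.5)
  expect_false(qc$trials$dropped_missing[1])

  # 51% -> dropped
  v2 <- rep(TRUE, 17 * fs)
  v2[window_idx_test((seq_along(v2) - 1) / fs, 2, 5.06)] <- FALSE
  qc2 <- reject_missing(mk_series(rnorm(17 * fs), v2), ev,
                        preprocess_params(pad_ms = 0))
  expect_true(qc2$trials$dropped_missing[1])
  expect_false(qc2$trials$dropped_missing[2])

  # session rule: exactly 15% kept, above dropped
  n <- 1000 * 20
  v3 <- rep(TRUE, n); v3[seq_len(0.15 * n)] <- FALSE
  ev3 <- data.frame(participant_id = "P1", trial_index = 1,
                    condition = "reward", fixation_onset_s = 50,
                    cue_onset_s = 55, cue_offset_s = 61,
                    feedback_onset_s = NA, feedback_success = NA)
  s3 <- mk_series(rnorm(n), v3)
  expect_false(reject_missing(s3, ev3)$session_dropped)
  v3[seq_len(0.151 * n)] <- FALSE
  expect_true(reject_missing(mk_series(rnorm(n), v3), ev3)$session_dropped)

  # events outside the recording are an error
  ev_bad <- ev; ev_bad$cue_offset_s[2] <- 1e4
  expect_error(reject_missing(s, ev_bad), "outside the recorded session")
})

test_that("interpolated blink samples still count as missing", {
  fs <- 250
  ev <- data.frame(participant_id = "P1", trial_index = 1,
                   condition = "reward", fixation_onset_s = 0.5,
                   cue_onset_s = 1, cue_offset_s = 7,
                   feedback_onset_s = NA, feedback_success = NA)
  v <- rep(TRUE, 9 * fs)
  v[window_idx_test((seq_along(v) - 1) / fs, 2, 3)] <- FALSE
  s <- interpolate_blinks(mk_series(rnorm(9 * fs), v), pad_ms = 100)
  expect_true(all(!is.na(s$pupil[v])))  # recovered numerically
  qc <- reject_missing(s, ev, preprocess_params())
  # 1 s blink + 2 x 100 ms padding inside a 6 s window
  expect_equal(qc$trials$trial_missing_fraction, 1.2 / 6, tolerance = 0.01)
  qc_raw <- reject_missing(s, ev,
                           preprocess_params(missing_counts_interpolated = FALSE))
  expect_equal(qc_raw$trials$trial_missing_fraction, 1 / 6, tolerance = 0.01)
})

test_that("gaze window fitting pools per-participant dispersion", {
  # two participants with gaze SDs 10 and 20 px: shared half-width 3.3 x 15
  fs <- 50
  n <- 20 * fs
  ev <- data.frame(participant_id = c("A", "B"), trial_index = 1,
                   condition = "reward", fixation_onset_s = 0.5,
                   cue_onset_s = 1, cue_offset_s = 7,
                   feedback_onset_s = NA, feedback_success = NA)
  set.seed(21)
  mk <- function(id, sd_px, cx) {
    s <- mk_series(rnorm(n), fs = fs,
                   gx = cx + rnorm(n, 0, sd_px), gy = 384 + rnorm(n, 0, sd_px))
    s$participant_id <- id
    s
  }
  samples <- list(A = mk("A", 10, 500), B = mk("B", 20, 520))
  gw <- fit_gaze_window(samples, ev)
  sd_emp <- mean(c(sd(samples$A$gaze_x_px[window_idx_test(samples$A$time_s, 1, 7)]),
                   sd(samples$B$gaze_x_px[window_idx_test(samples$B$time_s, 1, 7)])))
  expect_equal(gw$half_width_x_px[1], 3.3 * sd_emp, tolerance = 1e-12)
  expect_equal(gw$half_width_x_px, gw$half_width_x_px[c(1, 1)])  # cohort-level
  expect_equal(gw$center_x_px, c(500, 520), tolerance = 2)

  # constant gaze: well-defined centres but degenerate half-widths, which
  # the rejection step must refuse to use
  samples0 <- list(A = mk_series(rnorm(n), fs = fs),
                   B = mk_series(rnorm(n), fs = fs))
  samples0$B$participant_id <- "B"
  gw0 <- fit_gaze_window(samples0, ev)
  expect_equal(gw0$center_x_px, c(512, 512))
  expect_equal(gw0$half_width_x_px, c(0, 0))
  expect_error(reject_gaze(samples0$A, ev[1, ], gw0[1, ]), "degenerate")
})

test_that("gaze rejection drops trials above one cumulative second outside", {
  fs <- 250
  ev <- data.frame(participant_id = "P1", trial_index = 1:2,
                   condition = c("reward", "neutral"),
                   fixation_onset_s = c(1, 10), cue_onset_s = c(2, 11),
                   cue_offset_s = c(8, 17), feedback_onset_s = c(8.5, 17.5),
                   feedback_success = TRUE)
  n <- 20 * fs
  set.seed(5)
  win <- data.frame(participant_id = "P1", center_x_px = 512,
                    center_y_px = 384, half_width_x_px = 50,
                    half_height_y_px = 50)
  gx <- rep(512, n)
  t <- (seq_len(n) - 1) / fs
  gx[window_idx_test(t, 3, 4.2)] <- 700    # 1.2 s planted outside, trial 1
  gx[window_idx_test(t, 12, 12.8)] <- 700  # 0.8 s planted outside, trial 2
  s <- mk_series(rnorm(n), gx = gx)
  gz <- reject_gaze(s, ev, win)
  expect_equal(gz$out_of_window_s, c(1.2, 0.8))
  expect_identical(gz$dropped_gaze, c(TRUE, FALSE))

  # gaze always at centre: nothing dropped
  gz0 <- reject_gaze(mk_series(rnorm(n)), ev, win)
  expect_equal(gz0$out_of_window_s, c(0, 0))

  # consecutive rule: two separated 0.7 s episodes stay below a 1 s run
  gx2 <- rep(512, n)
  gx2[window_idx_test(t, 2.5, 3.2)] <- 700
  gx2[window_idx_test(t, 5, 5.7)] <- 700
  s2 <- mk_series(rnorm(n), gx = gx2)
  expect_true(reject_gaze(s2, ev, win)$dropped_gaze[1])
  expect_false(reject_gaze(s2, ev, win,
                           preprocess_params(gaze_rule = "consecutive"))$dropped_gaze[1])

  # only valid samples accumulate outside time
  v <- rep(TRUE, n)
  v[window_idx_test(t, 3, 3.6)] <- FALSE  # blink over half the excursion
  s3 <- mk_series(rnorm(n), valid = v, gx = gx)
  expect_equal(reject_gaze(s3, ev, win)$out_of_window_s[1], 0.6)
})

test_that("planted artifacts are dropped exactly, and only they", {
  st <- fx_study_planted_drop()
  cl <- preprocess_study(st$samples, st$events)
  tr <- st$truth$trials
  qc <- merge(cl$qc_trials, tr, by = c("participant_id", "trial_index"))
  expect_identical(qc$drop_reason == "missing", qc$expected_drop_missing)
  gaze_expected <- !qc$expected_drop_missing & qc$expected_drop_gaze
  expect_identical(qc$drop_reason == "gaze", gaze_expected)
  expect_gt(sum(qc$expected_drop_missing), 0)
  expect_gt(sum(gaze_expected), 0)

  # 0.8 s excursions never trip the 1 s rule
  st2 <- fx_study_planted_keep()
  cl2 <- preprocess_study(st2$samples, st2$events)
  expect_equal(sum(cl2$qc_trials$drop_reason == "gaze"), 0)
  expect_gt(sum(st2$truth$trials$excursion), 0)

  # a high-blink-rate participant exceeds the 15% session rule
  st3 <- simulate_study(sim_config(n_participants = 3, blink_rate = 35,
                                   seed = 606))
  cl3 <- preprocess_study(st3$samples, st3$events)
  expect_identical(cl3$qc_sessions$session_dropped,
                   st3$truth$participants$expected_session_drop)
  expect_gt(sum(cl3$qc_sessions$session_dropped), 0)
})

test_that("the chain preserves structure and partitions trials", {
  st <- fx_study_small()
  cl <- fx_clean_small()
  for (id in names(st$samples)) {
    raw <- st$samples[[id]]
    out <- cl$sessions[[id]]
    expect_equal(nrow(out), nrow(raw))           # smoothing preserves length
    expect_identical(out$valid, raw$valid)       # validity flags untouched
    expect_identical(out$gaze_x_px, raw$gaze_x_px)
  }
  qc <- cl$qc_trials
  for (id in unique(qc$participant_id)) {
    q <- qc[qc$participant_id == id, ]
    kept <- q$trial_index[!q$dropped]
    dropped <- q$trial_index[q$dropped]
    expect_equal(sort(c(kept, dropped)), 1:30)   # partition, disjoint
  }
  expect_equal(nrow(qc), 6 * 30)
  expect_true(all(qc$drop_reason[qc$dropped] != "none"))
  expect_true(all(qc$drop_reason[!qc$dropped] == "none"))
  # interpolation never changes valid, unpadded samples
  interp <- interpolate_blinks(st$samples[[1]], pad_ms = 100)
  untouched <- interp$valid & !interp$interpolated
  expect_equal(interp$pupil[untouched], st$samples[[1]]$pupil[untouched])
  # re-running is bit-identical
  cl2 <- preprocess_study(st$samples, st$events)
  expect_identical(cl2$sessions, cl$sessions)
  expect_identical(cl2$qc_trials, cl$qc_trials)
  expect_identical(cl2$manifest$config_hash, cl$manifest$config_hash)
})
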