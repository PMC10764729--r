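#' Preprocessing thresholds and rule switches
#'
#' Collects every tunable of the cleaning/QC chain. Defaults implement the
#' conventional rules for this task design: 100 ms interpolation padding
#' around blinks, a 200 ms
#' sliding-mean window, trials dropped when strictly more than 50% of the
#' anticipation window is missing, sessions dropped above 15% whole-session
#' missingness, a rectangular gaze window of 3.3 cohort-mean SDs around each
#' participant's median gaze, and trial rejection after more than one
#' cumulative second outside that window. The three switches cover readings
#' the original description leaves open.
#'
#' @param pad_ms Interpolation padding around each blink, ms.
#' @param window_ms Sliding-mean smoothing window (total width), ms.
#' @param trial_missing_threshold Strict trial-level missingness bound.
#' @param session_missing_threshold Strict session-level missingness bound.
#' @param gaze_sd_multiplier Half-width of the gaze window in cohort SDs.
#' @param max_outside_s Strict bound on time outside the gaze window, s.
#' @param missing_counts_interpolated If `TRUE` (default) interpolated blink
#'   samples still count as missing for the missingness fractions.
#' @param gaze_rule `"cumulative"` (default) sums all outside time in a
#'   trial; `"consecutive"` uses the longest uninterrupted outside run.
#' @param trial_missing_window `"anticipation"` (default) computes trial
#'   missingness over the 6-s cue window; `"trial"` over fixation onset to
#'   feedback offset (or cue offset where there is no feedback).
#' @param feedback_s Feedback display length used by the `"trial"` window.
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(pad_ms = 100, window_ms = 200,
                              trial_missing_threshold = 0.5,
                              session_missing_threshold = 0.15,
                              gaze_sd_multiplier = 3.3,
                              max_outside_s = 1.0,
                              missing_counts_interpolated = TRUE,
                              gaze_rule = c("cumulative", "consecutive"),
                              trial_missing_window = c("anticipation", "trial"),
                              feedback_s = 1.5) {
  stop_if_not(pad_ms >= 0, "pad_ms must be >= 0")
  stop_if_not(window_ms > 0, "window_ms must be > 0")
  stop_if_not(trial_missing_threshold > 0 && trial_missing_threshold < 1,
              "trial_missing_threshold must lie in (0, 1)")
  stop_if_not(session_missing_threshold > 0 && session_missing_threshold < 1,
              "session_missing_threshold must lie in (0, 1)")
  stop_if_not(gaze_sd_multiplier > 0, "gaze_sd_multiplier must be > 0")
  stop_if_not(max_outside_s > 0, "max_outside_s must be > 0")
  p <- list(pad_ms = pad_ms, window_ms = window_ms,
            trial_missing_threshold = trial_missing_threshold,
            session_missing_threshold = session_missing_threshold,
            gaze_sd_multiplier = gaze_sd_multiplier,
            max_outside_s = max_outside_s,
            missing_counts_interpolated = isTRUE(missing_counts_interpolated),
            gaze_rule = match.arg(gaze_rule),
            trial_missing_window = match.arg(trial_missing_window),
            feedback_s = feedback_s)
  class(p) <- "preprocess_params"
  p
}

series_rate <- function(series) {
  fs <- attr(series, "sampling_rate_hz")
  if (is.null(fs)) fs <- 1 / stats::median(diff(series$time_s))
  fs
}

#' Linearly interpolate blinks
#'
#' A blink is any contiguous run of `valid = FALSE` samples. For each run the
#' pupil trace is replaced by the straight line between the last valid sample
#' at least `pad_ms` before the run start and the first valid sample at least
#' `pad_ms` after the run end; every replaced sample (including the padded,
#' originally valid ones) is marked in a new `interpolated` column so the
#' missingness accounting can still count it as missing. Runs whose padding
#' reaches a session boundary are left missing.
#'
#' @param series A per-participant sample table (with `sampling_rate_hz`
#'   attribute), as returned by [read_samples()] or [simulate_study()].
#' @param pad_ms Padding before/after each blink, ms.
#' @return The series with interpolated pupil values and an `interpolated`
#'   column.
#' @export
interpolate_blinks <- function(series, pad_ms = 100) {
  stop_if_not(pad_ms >= 0, "pad_ms must be >= 0")
  stop_if_not(any(series$valid), "entire series is invalid; nothing to anchor on")
  n <- nrow(series)
  t <- series$time_s
  pupil <- series$pupil
  interpolated <- rep(FALSE, n)
  runs <- logical_runs(!series$valid)
  fs <- series_rate(series)
  pad_n <- as.integer(ceiling(pad_ms / 1000 * fs - 1e-6))
  if (nrow(runs) > 0) {
    # uniform grid: the pad_ms requirement is an index offset, and the
    # nearest valid sample at/before (at/after) any index is a cumulative max
    # (min) lookup
    idx <- seq_len(n)
    w <- integer(n)
    w[series$valid] <- idx[series$valid]
    prev_valid <- cummax(w)
    w <- integer(n)
    w[series$valid] <- n + 1L - idx[series$valid]
    next_valid <- n + 1L - rev(cummax(rev(w)))
    for (r in seq_len(nrow(runs))) {
      s0 <- runs$start[r]; s1 <- runs$end[r]
      a <- if (s0 - pad_n >= 1) prev_valid[s0 - pad_n] else 0L
      b <- if (s1 + pad_n <= n) next_valid[s1 + pad_n] else n + 1L
      if (a == 0L || b == n + 1L) {
        pupil[s0:s1] <- NA_real_  # boundary blink: stays missing
        next
      }
      fill <- (a + 1L):(b - 1L)
      pupil[fill] <- pupil[a] + (pupil[b] - pupil[a]) *
        (t[fill] - t[a]) / (t[b] - t[a])
      interpolated[fill] <- TRUE
    }
  }
  series$pupil <- pupil
  series$interpolated <- interpolated
  series
}

#' Sliding-mean smoothing
#'
#' Replaces every pupil sample by the mean of all samples within half the
#' window on each side (200 ms total by default, i.e. 100 ms before and
#' after). Windows are truncated at the series edges; missing samples are
#' excluded from the mean, and a sample with no usable neighbours stays
#' missing. Gaze and validity columns are untouched.
#'
#' @inheritParams interpolate_blinks
#' @param window_ms Total window width, ms.
#' @return The smoothed series.
#' @export
smooth_sliding_mean <- function(series, window_ms = 200) {
  stop_if_not(window_ms > 0, "window_ms must be > 0")
  fs <- series_rate(series)
  h <- as.integer(floor(window_ms / 2 * fs / 1000 + 1e-9))
  x <- series$pupil
  if (h == 0) return(series)
  n <- length(x)
  ok <- !is.na(x)
  x0 <- x
  x0[!ok] <- 0
  cs <- c(0, cumsum(x0))
  cn <- c(0, cumsum(as.numeric(ok)))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  cnts <- cn[hi + 1L] - cn[lo]
  sm <- (cs[hi + 1L] - cs[lo]) / cnts   # 0/0 -> NaN where no usable neighbour
  sm[cnts == 0] <- NA_real_
  series$pupil <- sm
  series
}

#' Session-level z-transform
#'
#' Standardizes the pupil trace to mean 0 and sample SD 1 (n-1 denominator)
#' over all usable samples (valid and interpolated alike; unrecovered missing
#' samples are excluded and stay missing). The applied centre and scale are
#' stored as attributes `zscore_center` and `zscore_scale`.
#'
#' @inheritParams interpolate_blinks
#' @return The standardized series.
#' @export
zscore_session <- function(series) {
  x <- series$pupil
  ok <- !is.na(x)
  stop_if_not(sum(ok) >= 2, "need at least 2 usable samples to z-transform")
  m <- mean(x[ok])
  s <- stats::sd(x[ok])
  stop_if_not(is.finite(s) && s > 0, "zero variance: cannot z-transform")
  series$pupil <- (x - m) / s
  attr(series, "zscore_center") <- m
  attr(series, "zscore_scale") <- s
  series
}

trial_window_bounds <- function(ev_row, params) {
  if (params$trial_missing_window == "trial") {
    to <- if (is.na(ev_row$feedback_onset_s)) ev_row$cue_offset_s
          else ev_row$feedback_onset_s + params$feedback_s
    c(ev_row$fixation_onset_s, to)
  } else {
    c(ev_row$cue_onset_s, ev_row$cue_offset_s)
  }
}

#' Missingness-based rejection
#'
#' Computes missing-data fractions on the raw validity flags; interpolated
#' blink samples count as missing by default. A trial is dropped when its
#' anticipation-window missing fraction is strictly greater than the trial
#' threshold; the whole session is dropped when its full-session missing
#' fraction is strictly greater than the session threshold.
#'
#' @inheritParams interpolate_blinks
#' @param events Event-table rows for this participant.
#' @param params A [preprocess_params()].
#' @return A list with `trials` (per-trial fractions and drop decisions),
#'   `session_missing_fraction` and `session_dropped`.
#' @export
reject_missing <- function(series, events, params = preprocess_params()) {
  miss <- !series$valid
  if (params$missing_counts_interpolated && !is.null(series$interpolated))
    miss <- miss | series$interpolated
  t_max <- max(series$time_s) + 1 / series_rate(series)
  stop_if_not(all(events$cue_offset_s <= t_max + 1e-9) &&
                all(events$fixation_onset_s >= series$time_s[1] - 1e-9),
              "events reference times outside the recorded session")
  frac <- vapply(seq_len(nrow(events)), function(k) {
    w <- trial_window_bounds(events[k, ], params)
    jj <- window_idx(series$time_s, w[1], w[2])
    stop_if_not(length(jj) > 0, "trial %d has no samples in its window",
                events$trial_index[k])
    mean(miss[jj])
  }, numeric(1))
  list(trials = data.frame(trial_index = events$trial_index,
                           trial_missing_fraction = frac,
                           dropped_missing = frac > params$trial_missing_threshold),
       session_missing_fraction = mean(miss),
       session_dropped = mean(miss) > params$session_missing_threshold)
}

#' Fit the cohort gaze window
#'
#' Per participant, the window centre is the median gaze (x, y) over all
#' anticipation-window samples with a valid eye signal; the rectangle
#' half-widths are shared across the cohort and equal
#' `gaze_sd_multiplier` times the cohort mean of the per-participant gaze
#' SDs in x and y.
#'
#' @param samples Named list of per-participant sample tables.
#' @param events Event table covering all participants.
#' @param params A [preprocess_params()].
#' @return A data frame with one row per participant: centre coordinates and
#'   the shared half-widths.
#' @export
fit_gaze_window <- function(samples, events, params = preprocess_params()) {
  stop_if_not(length(samples) >= 2, "need at least 2 participants")
  rows <- lapply(names(samples), function(id) {
    s <- samples[[id]]
    ev <- events[events$participant_id == id, , drop = FALSE]
    jj <- unlist(lapply(seq_len(nrow(ev)), function(k)
      window_idx(s$time_s, ev$cue_onset_s[k], ev$cue_offset_s[k])))
    jj <- jj[s$valid[jj]]
    stop_if_not(length(jj) > 0,
                "participant %s has no valid anticipation samples", id)
    data.frame(participant_id = id,
               center_x_px = stats::median(s$gaze_x_px[jj]),
               center_y_px = stats::median(s$gaze_y_px[jj]),
               sd_x = stats::sd(s$gaze_x_px[jj]),
               sd_y = stats::sd(s$gaze_y_px[jj]))
  })
  out <- do.call(rbind, rows)
  out$half_width_x_px <- params$gaze_sd_multiplier * mean(out$sd_x)
  out$half_height_y_px <- params$gaze_sd_multiplier * mean(out$sd_y)
  out
}

#' Gaze-window rejection
#'
#' Accumulates, per trial, the time (valid samples only) the gaze spends
#' outside the participant's rectangular window during the anticipation
#' window, and drops trials strictly above `max_outside_s`. With
#' `gaze_rule = "consecutive"` the longest uninterrupted outside run is used
#' instead of the cumulative sum.
#'
#' @inheritParams reject_missing
#' @param window One row of the [fit_gaze_window()] table for this
#'   participant.
#' @return A data frame with per-trial `out_of_window_s` and `dropped_gaze`.
#' @export
reject_gaze <- function(series, events, window, params = preprocess_params()) {
  stop_if_not(window$half_width_x_px > 0 && window$half_height_y_px > 0,
              "degenerate gaze window: half-widths must be positive")
  fs <- series_rate(series)
  outside <- series$valid &
    (abs(series$gaze_x_px - window$center_x_px) > window$half_width_x_px |
       abs(series$gaze_y_px - window$center_y_px) > window$half_height_y_px)
  secs <- vapply(seq_len(nrow(events)), function(k) {
    jj <- window_idx(series$time_s, events$cue_onset_s[k], events$cue_offset_s[k])
    o <- outside[jj]
    if (params$gaze_rule == "consecutive") {
      runs <- logical_runs(o)
      if (nrow(runs) == 0) 0 else max(runs$end - runs$start + 1L) / fs
    } else sum(o) / fs
  }, numeric(1))
  data.frame(trial_index = events$trial_index, out_of_window_s = secs,
             dropped_gaze = secs > params$max_outside_s)
}

#' Run the full cleaning and QC chain on a study
#'
#' Fixed pipeline order: blink interpolation, sliding-mean smoothing, session
#' z-transform; missingness QC is evaluated on the pre-smoothing validity and
#' interpolation flags, gaze QC against the cohort gaze window. Re-running on
#' the same input is bit-identical (no randomness is involved).
#'
#' @param samples Named list of per-participant sample tables.
#' @param events Event table for all participants.
#' @param params A [preprocess_params()].
#' @return A list of class `pupil_clean`: `sessions` (cleaned series),
#'   `qc_trials` (one row per trial: missing fraction, outside seconds,
#'   `dropped`, `drop_reason` in `missing`/`gaze`/`none`), `qc_sessions`,
#'   `gaze_windows` and a `manifest` echoing every threshold.
#' @export
preprocess_study <- function(samples, events, params = preprocess_params()) {
  stopifnot(inherits(params, "preprocess_params"))
  ids <- names(samples)
  interp <- lapply(samples, interpolate_blinks, pad_ms = params$pad_ms)
  gaze_win <- fit_gaze_window(samples, events, params)

  sessions <- vector("list", length(ids)); names(sessions) <- ids
  qc_trials <- vector("list", length(ids))
  qc_sessions <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    ev <- events[events$participant_id == id, , drop = FALSE]
    miss <- reject_missing(interp[[id]], ev, params)
    gz <- reject_gaze(interp[[id]], ev, gaze_win[gaze_win$participant_id == id, ],
                      params)
    drop_reason <- ifelse(miss$trials$dropped_missing, "missing",
                          ifelse(gz$dropped_gaze, "gaze", "none"))
    qc_trials[[i]] <- data.frame(
      participant_id = id, trial_index = ev$trial_index,
      condition = ev$condition,
      trial_missing_fraction = miss$trials$trial_missing_fraction,
      out_of_window_s = gz$out_of_window_s,
      dropped = drop_reason != "none", drop_reason = drop_reason,
      stringsAsFactors = FALSE)
    qc_sessions[[i]] <- data.frame(
      participant_id = id,
      session_missing_fraction = miss$session_missing_fraction,
      session_dropped = miss$session_dropped, stringsAsFactors = FALSE)
    sessions[[id]] <- zscore_session(
      smooth_sliding_mean(interp[[id]], window_ms = params$window_ms))
  }
  manifest <- c(list(pipeline = "interpolate>smooth>zscore>qc"),
                unclass(params))
  manifest$config_hash <- fnv1a32(paste(names(manifest),
                                        vapply(manifest, paste, character(1),
                                               collapse = ","), sep = "="))
  out <- list(sessions = sessions,
              qc_trials = do.call(rbind, qc_trials),
              qc_sessions = do.call(rbind, qc_sessions),
              gaze_windows = gaze_win, manifest = manifest, params = params)
  rownames(out$qc_trials) <- NULL
  rownames(out$qc_sessions) <- NULL
  class(out) <- "pupil_clean"
  out
}

#' @export
print.pupil_clean <- function(x, ...) {
  cat("<pupil_clean>\n")
  cat(sprintf("  %d sessions (%d dropped), %d trials (%d dropped: %d missing, %d gaze)\n",
              nrow(x$qc_sessions), sum(x$qc_sessions$session_dropped),
              nrow(x$qc_trials), sum(x$qc_trials$dropped),
              sum(x$qc_trials$drop_reason == "missing"),
              sum(x$qc_trials$drop_reason == "gaze")))
  invisible(x)
}
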