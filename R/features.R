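#' Pupil dilation of a trial segment
#'
#' Dilation is the mean first derivative of the (z-scored) pupil trace over
#' an analysis window: first differences divided by the sample period,
#' averaged across the window, in z-units per second. For a gap-free segment
#' this telescopes to `(last - first) / elapsed time`; missing differences
#' (around unrecovered gaps) are excluded from the mean.
#'
#' @param segment Numeric pupil samples covering the analysis window.
#' @param sampling_rate Sampling rate in Hz.
#' @return Dilation in z/s (`NA` if no usable difference remains).
#' @export
compute_dilation <- function(segment, sampling_rate) {
  stop_if_not(length(segment) >= 2, "segment must contain at least 2 samples")
  stop_if_not(sampling_rate > 0, "sampling_rate must be positive")
  d <- diff(segment) * sampling_rate
  if (all(is.na(d))) return(NA_real_)
  mean(d, na.rm = TRUE)
}

phase_segment <- function(series, from, to) {
  jj <- window_idx(series$time_s, from, to)
  series$pupil[jj]
}

#' Per-trial dilation table
#'
#' Computes the dilation of every surviving trial for the anticipation,
#' fixation and consumption phases of the task. Consumption rows exist only
#' for reward/neutral trials with successful (fast-enough) feedback.
#'
#' @param clean A `pupil_clean` object from [preprocess_study()].
#' @param events Event table for all participants.
#' @param feedback_s Feedback display duration in seconds.
#' @return A data frame with one row per surviving trial and columns
#'   `dilation_anticipation`, `dilation_fixation`, `dilation_consumption`.
#' @export
trial_dilations <- function(clean, events, feedback_s = 1.5) {
  stopifnot(inherits(clean, "pupil_clean"))
  keep_sessions <- clean$qc_sessions$participant_id[!clean$qc_sessions$session_dropped]
  rows <- list()
  for (id in keep_sessions) {
    s <- clean$sessions[[id]]
    fs <- series_rate(s)
    ev <- events[events$participant_id == id, , drop = FALSE]
    ev <- ev[order(ev$trial_index), , drop = FALSE]
    # within-condition trial number over ALL trials (so halves stay 1-5 / 6-10
    # even when QC removes trials), then restrict to surviving trials
    ev$cond_trial_index <- stats::ave(seq_len(nrow(ev)), ev$condition,
                                      FUN = seq_along)
    qc <- clean$qc_trials[clean$qc_trials$participant_id == id, , drop = FALSE]
    kept <- qc$trial_index[!qc$dropped]
    ev <- ev[ev$trial_index %in% kept, , drop = FALSE]
    if (nrow(ev) == 0) next
    ant <- vapply(seq_len(nrow(ev)), function(k)
      compute_dilation(phase_segment(s, ev$cue_onset_s[k], ev$cue_offset_s[k]), fs),
      numeric(1))
    fix <- vapply(seq_len(nrow(ev)), function(k)
      compute_dilation(phase_segment(s, ev$fixation_onset_s[k], ev$cue_onset_s[k]), fs),
      numeric(1))
    con <- vapply(seq_len(nrow(ev)), function(k) {
      if (is.na(ev$feedback_onset_s[k]) || !isTRUE(ev$feedback_success[k]))
        return(NA_real_)
      compute_dilation(phase_segment(s, ev$feedback_onset_s[k],
                                     ev$feedback_onset_s[k] + feedback_s), fs)
    }, numeric(1))
    rows[[id]] <- data.frame(
      participant_id = id, trial_index = ev$trial_index,
      condition = ev$condition, cond_trial_index = ev$cond_trial_index,
      dilation_anticipation = ant, dilation_fixation = fix,
      dilation_consumption = con, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

cell_mean <- function(x) if (length(x) == 0 || all(is.na(x))) NA_real_ else
  mean(x, na.rm = TRUE)

#' Per-participant feature rows
#'
#' Averages per-trial dilations into the per-participant scalar readouts the
#' statistics consume: per-condition anticipation dilation, differential
#' scores (reward minus control, reward minus neutral), fixation-phase
#' dilations (per condition and combined, plus their reward-minus-control
#' difference) and consumption-phase dilations (successful reward/neutral
#' feedback only). Sessions dropped by QC are omitted; a participant with no
#' surviving trial in a condition keeps their row with that cell `NA`.
#'
#' @inheritParams trial_dilations
#' @return A feature data frame, one row per surviving participant.
#' @export
aggregate_features <- function(clean, events, feedback_s = 1.5) {
  td <- trial_dilations(clean, events, feedback_s = feedback_s)
  ids <- unique(td$participant_id)
  rows <- lapply(ids, function(id) {
    d <- td[td$participant_id == id, , drop = FALSE]
    by_cond <- function(cond, col) cell_mean(d[[col]][d$condition == cond])
    n_used <- function(cond) sum(d$condition == cond &
                                   !is.na(d$dilation_anticipation))
    r <- by_cond("reward", "dilation_anticipation")
    nn <- by_cond("neutral", "dilation_anticipation")
    cc <- by_cond("control", "dilation_anticipation")
    data.frame(
      participant_id = id,
      dilation_reward = r, dilation_neutral = nn, dilation_control = cc,
      diff_reward_minus_control = r - cc,
      diff_reward_minus_neutral = r - nn,
      dilation_fixation_reward = by_cond("reward", "dilation_fixation"),
      dilation_fixation_neutral = by_cond("neutral", "dilation_fixation"),
      dilation_fixation_control = by_cond("control", "dilation_fixation"),
      dilation_fixation_all = cell_mean(d$dilation_fixation),
      diff_fixation_reward_minus_control =
        by_cond("reward", "dilation_fixation") - by_cond("control", "dilation_fixation"),
      dilation_consumption_reward = by_cond("reward", "dilation_consumption"),
      dilation_consumption_neutral = by_cond("neutral", "dilation_consumption"),
      n_trials_reward = n_used("reward"), n_trials_neutral = n_used("neutral"),
      n_trials_control = n_used("control"),
      n_trials_consumption_reward = sum(d$condition == "reward" &
                                          !is.na(d$dilation_consumption)),
      n_trials_consumption_neutral = sum(d$condition == "neutral" &
                                           !is.na(d$dilation_consumption)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Split-half reliability of the differential dilation score
#'
#' Per participant, the reward-minus-control differential anticipation
#' dilation is computed separately from each condition's first half of trials
#' (within-condition trial numbers 1-5 for 10 trials per condition) and from
#' the second half; the split-half reliability is the Pearson correlation of
#' the two half scores across participants. No Spearman-Brown correction is
#' applied: the uncorrected coefficient is the quantity plugged into the
#' measurement-error model.
#'
#' @param td A per-trial dilation table from [trial_dilations()] (columns
#'   `participant_id`, `condition`, `cond_trial_index`,
#'   `dilation_anticipation`).
#' @param n_trials_per_condition Nominal trials per condition (halves split
#'   at `n_trials_per_condition / 2`).
#' @return The split-half correlation.
#' @export
split_half_reliability <- function(td, n_trials_per_condition = 10) {
  half <- n_trials_per_condition / 2
  per_part <- lapply(split(td, td$participant_id), function(d) {
    score <- function(first_half) {
      sel <- if (first_half) d$cond_trial_index <= half else d$cond_trial_index > half
      r <- cell_mean(d$dilation_anticipation[sel & d$condition == "reward"])
      c0 <- cell_mean(d$dilation_anticipation[sel & d$condition == "control"])
      r - c0
    }
    c(score(TRUE), score(FALSE))
  })
  m <- do.call(rbind, per_part)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  stop_if_not(nrow(m) >= 3,
              "need at least 3 participants with both halves in both conditions")
  stats::cor(m[, 1], m[, 2])
}

#' Derive clinical records
#'
#' Adds the BDI-II anhedonia score (items 4 + 12 + 21) and the acute flag
#' (MDD group with five or more depressive symptoms in the last two weeks).
#'
#' @param clinical A clinical table as returned by [read_clinical()] or
#'   [simulate_study()].
#' @return The table with `anhedonia_score` and `acute` columns.
#' @export
derive_clinical <- function(clinical) {
  items <- sprintf("bdi_item_%02d", c(4, 12, 21))
  stop_if_not(all(items %in% names(clinical)),
              "clinical table lacks BDI items 4/12/21")
  clinical$anhedonia_score <- clinical[[items[1]]] + clinical[[items[2]]] +
    clinical[[items[3]]]
  clinical$acute <- clinical$group == "MDD" & clinical$symptom_count >= 5
  clinical
}
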