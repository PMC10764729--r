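# Tabular data contracts: plain TSV, UTF-8, "." decimal, header row fixed.
# Readers validate and reject; they never coerce malformed input. Missing
# samples may be encoded either as an empty pupil field or as a present value
# with valid = FALSE; both are treated as missing on load.

num_cols_to_char <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
    df[[j]][df[[j]] %in% c("NA", "nan")] <- ""
  }
  df
}

write_tsv_contract <- function(df, path) {
  out <- num_cols_to_char(df)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                       row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok),
                        call. = FALSE)
  invisible(path)
}

read_tsv_contract <- function(path, required) {
  stop_if_not(file.exists(path), "file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "", fileEncoding = "UTF-8",
                          check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  stop_if_not(length(missing_cols) == 0, "%s: missing column(s): %s",
              path, paste(missing_cols, collapse = ", "))
  df
}

as_logical_col <- function(x, what) {
  if (is.logical(x)) return(x)
  v <- rep(NA, length(x))
  v[x %in% c("TRUE", "true", "1")] <- TRUE
  v[x %in% c("FALSE", "false", "0")] <- FALSE
  bad <- !is.na(x) & is.na(v)
  stop_if_not(!any(bad), "column %s is not boolean (first bad value: %s)",
              what, if (any(bad)) x[which(bad)[1]] else "")
  v
}

#' Read a pupil/gaze sample table
#'
#' Columns: `participant_id`, `time_s`, `pupil`, `gaze_x_px`, `gaze_y_px`,
#' `valid`. Per participant, `time_s` must be strictly increasing with a
#' constant sampling interval (1e-6 s tolerance). Pupil values on
#' `valid = FALSE` rows are set to `NA` regardless of what the file carries.
#'
#' @param path TSV file path.
#' @return A named list of per-participant data frames, each with attribute
#'   `sampling_rate_hz`.
#' @export
read_samples <- function(path) {
  req <- c("participant_id", "time_s", "pupil", "gaze_x_px", "gaze_y_px", "valid")
  df <- read_tsv_contract(path, req)
  df$valid <- as_logical_col(df$valid, "valid")
  stop_if_not(!any(is.na(df$valid)), "%s: valid flags must not be missing", path)
  df$pupil[!df$valid] <- NA_real_
  out <- split(df, df$participant_id)
  for (id in names(out)) {
    s <- out[[id]]
    rownames(s) <- NULL
    stop_if_not(nrow(s) >= 2, "participant %s: need at least 2 samples", id)
    dts <- diff(s$time_s)
    stop_if_not(all(dts > 0), "participant %s: time_s not strictly increasing", id)
    stop_if_not(max(dts) - min(dts) < 1e-6,
                "participant %s: non-uniform sampling interval", id)
    attr(s, "sampling_rate_hz") <- 1 / stats::median(dts)
    out[[id]] <- s
  }
  out
}

#' Read a trial event table
#'
#' Columns: `participant_id`, `trial_index` (1-based), `condition`
#' (reward/neutral/control), `fixation_onset_s`, `cue_onset_s`,
#' `cue_offset_s`, `feedback_onset_s` (empty for control),
#' `feedback_success` (empty for control). Validates the anticipation-window
#' duration and the phase ordering within each trial.
#'
#' @param path TSV file path.
#' @param anticipation_s Contracted cue window length in seconds.
#' @param sampling_rate Sampling rate used for the one-sample-period duration
#'   tolerance.
#' @return A data frame.
#' @export
read_events <- function(path, anticipation_s = 6, sampling_rate = 250) {
  req <- c("participant_id", "trial_index", "condition", "fixation_onset_s",
           "cue_onset_s", "cue_offset_s", "feedback_onset_s", "feedback_success")
  df <- read_tsv_contract(path, req)
  df$feedback_success <- as_logical_col(df$feedback_success, "feedback_success")
  bad_cond <- !df$condition %in% c("reward", "neutral", "control")
  stop_if_not(!any(bad_cond), "%s: unknown condition '%s' (participant %s, trial %s)",
              path, df$condition[which(bad_cond)[1]],
              df$participant_id[which(bad_cond)[1]],
              df$trial_index[which(bad_cond)[1]])
  stop_if_not(all(df$trial_index >= 1 & df$trial_index == round(df$trial_index)),
              "%s: trial_index must be 1-based integers", path)
  tol <- 1 / sampling_rate + 1e-9
  for (r in seq_len(nrow(df))) {
    dur <- df$cue_offset_s[r] - df$cue_onset_s[r]
    stop_if_not(abs(dur - anticipation_s) <= tol,
                "%s: cue window of %.4f s violates the %.4f s contract (participant %s, trial %d)",
                path, dur, anticipation_s, df$participant_id[r], df$trial_index[r])
    ord_ok <- df$fixation_onset_s[r] < df$cue_onset_s[r] &&
      df$cue_onset_s[r] < df$cue_offset_s[r] &&
      (is.na(df$feedback_onset_s[r]) || df$feedback_onset_s[r] >= df$cue_offset_s[r])
    stop_if_not(ord_ok, "%s: phases out of order (participant %s, trial %d)",
                path, df$participant_id[r], df$trial_index[r])
  }
  df
}

#' Read a clinical table
#'
#' Columns: `participant_id`, `group` (HC/MDD), `symptom_count` (integer
#' 0-20) and `bdi_item_01` ... `bdi_item_21` (integers 0-3). HC rows must
#' carry a symptom count of zero.
#'
#' @param path TSV file path.
#' @return A data frame.
#' @export
read_clinical <- function(path) {
  item_cols <- sprintf("bdi_item_%02d", 1:21)
  req <- c("participant_id", "group", "symptom_count", item_cols)
  df <- read_tsv_contract(path, req)
  bad_group <- !df$group %in% c("HC", "MDD")
  stop_if_not(!any(bad_group), "%s: group must be HC or MDD (participant %s)",
              path, df$participant_id[which(bad_group)[1]])
  bad_count <- is.na(df$symptom_count) | df$symptom_count < 0 |
    df$symptom_count > 20 | df$symptom_count != round(df$symptom_count)
  stop_if_not(!any(bad_count),
              "%s: symptom_count out of range 0-20 (participant %s, row %d)",
              path, df$participant_id[which(bad_count)[1]], which(bad_count)[1])
  for (cl in item_cols) {
    bad <- is.na(df[[cl]]) | df[[cl]] < 0 | df[[cl]] > 3 |
      df[[cl]] != round(df[[cl]])
    stop_if_not(!any(bad), "%s: %s out of range 0-3 (participant %s, row %d)",
                path, cl, df$participant_id[which(bad)[1]], which(bad)[1])
  }
  hc_bad <- df$group == "HC" & df$symptom_count != 0
  stop_if_not(!any(hc_bad),
              "%s: HC participants must report zero symptoms (participant %s)",
              path, df$participant_id[which(hc_bad)[1]])
  df
}

#' Write tables of the study contracts
#'
#' `write_features()` and its reader are round-trip stable to full double
#' precision; an empty feature list produces a header-only file.
#'
#' @param features A feature data frame as returned by [aggregate_features()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_features <- function(features, path) write_tsv_contract(features, path)

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read_tsv_contract(path, c("participant_id", "dilation_reward",
                                  "dilation_control", "diff_reward_minus_control"))
  df
}

#' Write or read a posterior summary table
#'
#' One row: posterior location and 95% credible interval of the latent
#' correlation, the directional Bayes factor (with its lower-bound flag when
#' no posterior draw crossed zero), and the MCMC diagnostics.
#'
#' @param fit A `latent_corr` fit from [fit_latent_correlation()].
#' @param path Output TSV path.
#' @return The path (writer) or a one-row data frame (reader).
#' @export
write_posterior_summary <- function(fit, path) {
  stopifnot(inherits(fit, "latent_corr"))
  write_tsv_contract(posterior_summary_row(fit), path)
}

#' @rdname write_posterior_summary
#' @export
read_posterior_summary <- function(path) {
  df <- read_tsv_contract(path, c("rho_mean", "rho_ci_lower", "rho_ci_upper",
                                  "bf_minus", "bf_is_lower_bound"))
  df$bf_is_lower_bound <- as_logical_col(df$bf_is_lower_bound, "bf_is_lower_bound")
  df
}

posterior_summary_row <- function(fit) {
  data.frame(n = fit$n, rho_mean = fit$summary["rho", "mean"],
             rho_median = fit$summary["rho", "median"],
             rho_ci_lower = fit$summary["rho", "q2.5"],
             rho_ci_upper = fit$summary["rho", "q97.5"],
             bf_minus = fit$bf_minus, bf_is_lower_bound = fit$bf_is_lower_bound,
             rhat_max = max(fit$rhat), ess_rho = fit$ess["rho"],
             n_chains = fit$chains, n_kept = fit$iter, seed = fit$seed,
             row.names = NULL)
}

#' Write a simulated study to a directory
#'
#' Emits `samples.tsv`, `events.tsv`, `clinical.tsv` plus the ground-truth
#' sidecars `truth_participants.tsv` and `truth_trials.tsv`.
#'
#' @param study A `pupil_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "pupil_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_contract(do.call(rbind, study$samples), file.path(dir, "samples.tsv"))
  write_tsv_contract(study$events, file.path(dir, "events.tsv"))
  write_tsv_contract(study$clinical, file.path(dir, "clinical.tsv"))
  write_tsv_contract(study$truth$participants,
                     file.path(dir, "truth_participants.tsv"))
  write_tsv_contract(study$truth$trials, file.path(dir, "truth_trials.tsv"))
  invisible(dir)
}

#' Flat key = value run-configuration files
#'
#' @param config A named list of scalar values.
#' @param path File path.
#' @return The path (writer) or a named list (reader); numbers and logicals
#'   are restored to their native types.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  vals <- vapply(config, function(v) paste(format(v, digits = 17), collapse = ","),
                 character(1))
  writeLines(paste(names(config), vals, sep = " = "), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  stop_if_not(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", lines))
  stop_if_not(all(lengths(kv) == 3), "malformed key = value line in %s", path)
  out <- lapply(kv, function(m) {
    parts <- strsplit(m[3], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num
    else if (all(parts %in% c("TRUE", "FALSE"))) as.logical(parts)
    else parts
  })
  names(out) <- vapply(kv, function(m) m[2], character(1))
  out
}
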