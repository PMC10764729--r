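# Stage orchestration: thin, deterministic glue over the module functions so
# simulated or real (TSV) data can enter at any stage. The numbered scripts
# under analysis/ are one-command drivers around these.

contrast_column <- function(contrast) {
  map <- c(reward_minus_control = "diff_reward_minus_control",
           reward_minus_neutral = "diff_reward_minus_neutral",
           reward = "dilation_reward",
           neutral = "dilation_neutral",
           control = "dilation_control",
           fixation_all = "dilation_fixation_all",
           fixation_reward = "dilation_fixation_reward",
           fixation_neutral = "dilation_fixation_neutral",
           fixation_control = "dilation_fixation_control",
           fixation_reward_minus_control = "diff_fixation_reward_minus_control",
           consumption_reward = "dilation_consumption_reward",
           consumption_neutral = "dilation_consumption_neutral")
  stop_if_not(contrast %in% names(map), "unknown contrast '%s'", contrast)
  map[[contrast]]
}

#' Latent correlation between a dilation contrast and a symptom score
#'
#' Joins features and clinical records, selects a participant subset and a
#' dilation contrast, attaches `SD * sqrt(1 - reliability)` measurement
#' uncertainty to both variables, and fits the measurement-error correlation
#' model. The pupil reliability defaults to the split-half plug-in 0.87 (pass
#' 0.70 for the conservative re-run); the symptom-count reliability defaults
#' to the published M-CIDI test-retest value 0.78. Pass `reliability_pupil =
#' NULL` to plug in the split-half reliability estimated from `trials` by
#' [split_half_reliability()].
#'
#' @param features Feature rows from [aggregate_features()].
#' @param clinical Clinical records (derived columns added if absent).
#' @param score `"symptom_count"` or `"anhedonia_score"`.
#' @param contrast Dilation contrast: `"reward_minus_control"` (default),
#'   `"reward_minus_neutral"`, a per-stimulus dilation (`"reward"`,
#'   `"neutral"`, `"control"`), a fixation-phase readout (`"fixation_all"`,
#'   `"fixation_reward"`, ..., `"fixation_reward_minus_control"`) or a
#'   consumption-phase readout (`"consumption_reward"`,
#'   `"consumption_neutral"`).
#' @param subset `"MDD"` (patients only, the replication analysis) or
#'   `"all"` (patients plus controls).
#' @param reliability_pupil Pupil reliability plug-in, or `NULL` to estimate
#'   it from `trials`.
#' @param reliability_symptoms Symptom-score reliability plug-in.
#' @param trials Optional per-trial dilation table (only needed when
#'   `reliability_pupil` is `NULL`).
#' @param priors,chains,iter,warmup,seed,rhat_max Passed to
#'   [fit_latent_correlation()].
#' @return A `latent_corr` fit; the subset/contrast/reliabilities used are
#'   attached as attribute `analysis`.
#' @export
correlate_dilation_symptoms <- function(features, clinical,
                                        score = c("symptom_count", "anhedonia_score"),
                                        contrast = "reward_minus_control",
                                        subset = c("MDD", "all"),
                                        reliability_pupil = 0.87,
                                        reliability_symptoms = 0.78,
                                        trials = NULL,
                                        priors = prior_spec(),
                                        chains = 4, iter = 5000, warmup = 1000,
                                        seed = 1, rhat_max = 1.01) {
  score <- match.arg(score)
  subset <- match.arg(subset)
  col <- contrast_column(contrast)
  if (!"anhedonia_score" %in% names(clinical))
    clinical <- derive_clinical(clinical)
  merged <- merge(features[, c("participant_id", col)], clinical,
                  by = "participant_id")
  if (subset == "MDD") merged <- merged[merged$group == "MDD", , drop = FALSE]
  merged <- merged[stats::complete.cases(merged[[col]], merged[[score]]), ,
                   drop = FALSE]
  stop_if_not(nrow(merged) >= 3, "fewer than 3 complete pairs after subsetting")

  if (is.null(reliability_pupil)) {
    stop_if_not(!is.null(trials),
                "trials table required to estimate the split-half reliability")
    reliability_pupil <- split_half_reliability(trials)
  }
  x <- merged[[col]]
  y <- merged[[score]]
  fit <- fit_latent_correlation(
    x, y,
    se_x = measurement_se(stats::sd(x), reliability_pupil),
    se_y = measurement_se(stats::sd(y), reliability_symptoms),
    priors = priors, chains = chains, iter = iter, warmup = warmup,
    seed = seed, rhat_max = rhat_max)
  attr(fit, "analysis") <- list(score = score, contrast = contrast,
                                subset = subset,
                                reliability_pupil = reliability_pupil,
                                reliability_symptoms = reliability_symptoms,
                                raw_pearson_r = stats::cor(x, y))
  fit
}

#' Bayesian group comparison of anticipation dilation
#'
#' Default-prior two-sample Bayes factor comparing mean reward-anticipation
#' dilation between healthy controls and either all depressed or only
#' acutely depressed (five or more symptoms) participants.
#'
#' @param features Feature rows.
#' @param clinical Clinical records.
#' @param which_depressed `"acute"` or `"all"`.
#' @param dilation_col Feature column compared between groups.
#' @return A `bf_result` from [bf10_ttest()].
#' @export
compare_groups_dilation <- function(features, clinical,
                                    which_depressed = c("acute", "all"),
                                    dilation_col = "dilation_reward") {
  which_depressed <- match.arg(which_depressed)
  if (!"acute" %in% names(clinical)) clinical <- derive_clinical(clinical)
  merged <- merge(features[, c("participant_id", dilation_col)], clinical,
                  by = "participant_id")
  hc <- merged[[dilation_col]][merged$group == "HC"]
  dep <- if (which_depressed == "acute")
    merged[[dilation_col]][merged$acute]
  else merged[[dilation_col]][merged$group == "MDD"]
  bf10_ttest(hc[!is.na(hc)], dep[!is.na(dep)])
}

#' Run the full simulate-preprocess-features-inference pipeline
#'
#' One call from a [sim_config()] to the replication-style outputs:
#' cleaned sessions and QC report, per-participant features, split-half
#' reliability, the latent-correlation fit of the differential dilation
#' against symptom count within patients, and (optionally) the BDI item
#' screen and HC-versus-acute group comparison. Deterministic given the
#' seeds carried by `config` and `seed`.
#'
#' @param config A [sim_config()].
#' @param params A [preprocess_params()].
#' @param score,subset,contrast Passed to [correlate_dilation_symptoms()].
#' @param reliability_pupil,reliability_symptoms Reliability plug-ins.
#' @param chains,iter,warmup MCMC layout.
#' @param seed Seed for the MCMC stage.
#' @param run_item_screen_stage,run_group_stage Toggle the extension stages.
#' @return A list of class `pupil_pipeline` with every stage's output and a
#'   run `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), params = preprocess_params(),
                         score = "symptom_count", subset = "MDD",
                         contrast = "reward_minus_control",
                         reliability_pupil = 0.87, reliability_symptoms = 0.78,
                         chains = 4, iter = 5000, warmup = 1000, seed = 1,
                         run_item_screen_stage = FALSE,
                         run_group_stage = FALSE) {
  study <- simulate_study(config)
  analyze_study(study, params = params, score = score, subset = subset,
                contrast = contrast, reliability_pupil = reliability_pupil,
                reliability_symptoms = reliability_symptoms, chains = chains,
                iter = iter, warmup = warmup, seed = seed,
                run_item_screen_stage = run_item_screen_stage,
                run_group_stage = run_group_stage)
}

#' @rdname run_pipeline
#' @param study A `pupil_study` (simulated, or assembled from TSVs read with
#'   the `read_*` functions plus a `config` describing the task timing).
#' @export
analyze_study <- function(study, params = preprocess_params(),
                          score = "symptom_count", subset = "MDD",
                          contrast = "reward_minus_control",
                          reliability_pupil = 0.87, reliability_symptoms = 0.78,
                          chains = 4, iter = 5000, warmup = 1000, seed = 1,
                          run_item_screen_stage = FALSE,
                          run_group_stage = FALSE) {
  clean <- preprocess_study(study$samples, study$events, params)
  trials <- trial_dilations(clean, study$events,
                            feedback_s = study$config$feedback_s %||% 1.5)
  features <- aggregate_features(clean, study$events,
                                 feedback_s = study$config$feedback_s %||% 1.5)
  clinical <- derive_clinical(study$clinical)
  r_half <- split_half_reliability(
    trials, n_trials_per_condition = study$config$n_trials_per_condition %||% 10)
  fit <- correlate_dilation_symptoms(
    features, clinical, score = score, contrast = contrast, subset = subset,
    reliability_pupil = reliability_pupil,
    reliability_symptoms = reliability_symptoms, trials = trials,
    chains = chains, iter = iter, warmup = warmup, seed = seed)

  items <- if (run_item_screen_stage) run_item_screen(features, clinical)
  groups <- if (run_group_stage)
    list(acute = compare_groups_dilation(features, clinical, "acute"),
         all = compare_groups_dilation(features, clinical, "all"))

  manifest <- c(list(seed = seed, chains = chains, iter = iter,
                     warmup = warmup, score = score, subset = subset,
                     contrast = contrast,
                     reliability_pupil = reliability_pupil,
                     reliability_symptoms = reliability_symptoms,
                     package_version = as.character(utils::packageVersion("pupilcorr"))),
                clean$manifest)
  out <- list(study = study, clean = clean, trials = trials,
              features = features, clinical = clinical,
              split_half = r_half, fit = fit, item_screen = items,
              group_comparisons = groups, manifest = manifest)
  class(out) <- "pupil_pipeline"
  out
}

#' Plain-text result report
#'
#' Formats the pipeline outputs as the blocks a study report needs: the
#' replication correlation with its directional Bayes factor, the QC
#' summary, the item screen (when run) and the group comparisons (when run).
#'
#' @param pipeline A `pupil_pipeline` from [run_pipeline()].
#' @return A character vector of report lines, invisibly; also printed.
#' @export
pipeline_report <- function(pipeline) {
  stopifnot(inherits(pipeline, "pupil_pipeline"))
  fit <- pipeline$fit
  an <- attr(fit, "analysis")
  s <- fit$summary["rho", ]
  lines <- c(
    "== pupilcorr pipeline report ==",
    sprintf("sessions: %d analysed, %d dropped (>15%% missing)",
            sum(!pipeline$clean$qc_sessions$session_dropped),
            sum(pipeline$clean$qc_sessions$session_dropped)),
    sprintf("trials dropped: %d missing, %d gaze (of %d)",
            sum(pipeline$clean$qc_trials$drop_reason == "missing"),
            sum(pipeline$clean$qc_trials$drop_reason == "gaze"),
            nrow(pipeline$clean$qc_trials)),
    sprintf("split-half reliability (trials 1-5 vs 6-10): %.3f",
            pipeline$split_half),
    "",
    sprintf("latent correlation, %s vs %s (%s subset, n = %d):",
            an$contrast, an$score, an$subset, fit$n),
    sprintf("  raw Pearson r = %.3f", an$raw_pearson_r),
    sprintf("  posterior rho: mean %.3f, 95%% CI [%.3f, %.3f]",
            s["mean"], s["q2.5"], s["q97.5"]),
    sprintf("  BF(-) = %.4g%s  [%s]", fit$bf_minus,
            if (fit$bf_is_lower_bound) " (lower bound)" else "",
            bf_evidence_label(max(fit$bf_minus, 1e-12))))
  if (!is.null(pipeline$item_screen)) {
    hits <- pipeline$item_screen[pipeline$item_screen$moderate_evidence, ]
    lines <- c(lines, "", "BDI-II item screen (BF10 > 3):",
               if (nrow(hits) == 0) "  none" else
                 sprintf("  %-36s r = %+.2f  BF10 = %.3g",
                         hits$label, hits$r, hits$bf10))
  }
  if (!is.null(pipeline$group_comparisons)) {
    g <- pipeline$group_comparisons
    lines <- c(lines, "", "group comparisons of reward dilation (HC vs depressed):",
               sprintf("  HC vs acutely depressed: BF10 = %.3g (%s)",
                       g$acute$bf10, g$acute$evidence),
               sprintf("  HC vs all depressed:     BF10 = %.3g (%s)",
                       g$all$bf10, g$all$evidence))
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}

#' @export
print.pupil_pipeline <- function(x, ...) {
  pipeline_report(x)
  invisible(x)
}
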