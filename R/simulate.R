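#' Configuration for a simulated reward-anticipation pupillometry study
#'
#' Bundles every knob of the synthetic-study generator. The task constants
#' default to the design of the reward-anticipation paradigm the package
#' analyses: 250 Hz monocular pupil recording, 30 trials (10 each of reward,
#' neutral and control condition), a 6-s cue/anticipation window and a 1.5-s
#' feedback display. Quantities the task description leaves open (fixation
#' jitter, flash-to-feedback gap, inter-trial interval) are exposed here and
#' documented as assumptions in the methods vignette.
#'
#' The generator plants a known latent structure: each participant carries an
#' arousal trait (standard normal) that scales the anticipation-window pupil
#' ramp, and a latent symptom burden correlated with the trait at
#' `true_rho`. The observed symptom count is a discretized, noisy measurement
#' of that burden calibrated so that its reliability with respect to the
#' burden equals `symptom_reliability`; trial-to-trial ramp jitter is
#' calibrated through the Spearman-Brown relation so that the split-half
#' (5 vs 5 trials) reliability of the differential dilation score equals
#' `reliability_target`.
#'
#' @param n_participants Number of participants (>= 2).
#' @param prop_depressed Expected fraction of participants with a nonzero
#'   symptom count (these form the MDD group; zero-count rows are HC).
#' @param true_rho Latent correlation in `[-1, 1]` between the arousal trait
#'   and the symptom burden; the planted association is `-|true_rho|`
#'   (higher trait = stronger dilation = fewer symptoms).
#' @param sampling_rate Sampling rate in Hz.
#' @param n_trials_per_condition Trials per condition.
#' @param anticipation_s Cue (anticipation window) duration in seconds.
#' @param feedback_s Feedback display duration in seconds.
#' @param fixation_s_range Length-2 range for the uniform fixation jitter (s).
#' @param flash_gap_s Gap between cue offset and feedback onset (flash plus
#'   response), seconds.
#' @param iti_s Inter-trial interval after feedback offset, seconds.
#' @param blink_rate Blink rate in blinks per minute.
#' @param blink_dur_ms_range Length-2 range of blink durations (ms).
#' @param gaze_center_px Screen centre the gaze stream fluctuates around.
#' @param gaze_noise_sd Gaze noise SD in px.
#' @param gaze_excursion_prob Per-trial probability of a planted out-of-window
#'   gaze episode inside the anticipation window.
#' @param gaze_excursion_px Horizontal offset of planted gaze episodes (px).
#' @param gaze_excursion_s_range Length-2 range of planted episode durations
#'   (s); set both ends equal for fixed-length plants in fixtures.
#' @param missing_trial_prob Per-trial probability of a planted long missing
#'   run (55% of the anticipation window) that the missingness QC must drop.
#' @param trial_noise_sd SD of the per-trial ramp-slope jitter (signal
#'   units/s). `NULL` (default) derives it from `reliability_target`.
#' @param sample_noise_sd White measurement noise added to every pupil sample.
#' @param reliability_target Target split-half reliability of the differential
#'   dilation score; used only when `trial_noise_sd` is `NULL`.
#' @param symptom_reliability Reliability of the observed symptom count with
#'   respect to the latent burden.
#' @param base_slopes Named numeric: population-mean anticipation ramp slopes
#'   (signal units/s) for reward, neutral and control cues.
#' @param trait_gains Named numeric: how strongly the arousal trait scales
#'   each condition's ramp slope.
#' @param baseline_level Tonic pupil level in arbitrary recorder units.
#' @param baseline_step_sd SD of the per-trial tonic baseline offset.
#' @param item_burden_loading Loading of every BDI item on the symptom burden.
#' @param trait_loaded_items BDI item numbers that additionally load on the
#'   arousal trait (the anhedonia/energy items the item screen should flag).
#' @param item_trait_loading Extra trait loading for `trait_loaded_items`.
#' @param seed Integer seed; the whole study is deterministic given it.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_study()]
#' @export
sim_config <- function(n_participants = 70,
                       prop_depressed = 40 / 70,
                       true_rho = -0.4,
                       sampling_rate = 250,
                       n_trials_per_condition = 10,
                       anticipation_s = 6,
                       feedback_s = 1.5,
                       fixation_s_range = c(2, 4),
                       flash_gap_s = 0.5,
                       iti_s = 1,
                       blink_rate = 12,
                       blink_dur_ms_range = c(100, 400),
                       gaze_center_px = c(512, 384),
                       gaze_noise_sd = 15,
                       gaze_excursion_prob = 0.05,
                       gaze_excursion_px = 400,
                       gaze_excursion_s_range = c(0.4, 1.6),
                       missing_trial_prob = 0.02,
                       trial_noise_sd = NULL,
                       sample_noise_sd = 0.1,
                       reliability_target = 0.87,
                       symptom_reliability = 0.78,
                       base_slopes = c(reward = 0.3, neutral = 0.2, control = 0.1),
                       trait_gains = c(reward = 0.15, neutral = 0.05, control = 0),
                       baseline_level = 5,
                       baseline_step_sd = 1,
                       item_burden_loading = 0.45,
                       trait_loaded_items = c(4, 15, 21),
                       item_trait_loading = 0.30,
                       seed = 1) {
  stop_if_not(is_count(n_participants), "n_participants must be a positive integer")
  stop_if_not(is_fraction(prop_depressed), "prop_depressed must lie in [0, 1]")
  stop_if_not(is.numeric(true_rho) && abs(true_rho) <= 1, "|true_rho| must be <= 1")
  stop_if_not(sampling_rate > 0, "sampling_rate must be positive")
  stop_if_not(is_count(n_trials_per_condition), "n_trials_per_condition must be a count")
  for (nm in c("anticipation_s", "feedback_s", "flash_gap_s", "iti_s"))
    stop_if_not(get(nm) > 0, "%s must be strictly positive", nm)
  stop_if_not(length(fixation_s_range) == 2 && all(fixation_s_range > 0) &&
                diff(fixation_s_range) >= 0, "invalid fixation_s_range")
  stop_if_not(blink_rate >= 0, "blink_rate must be >= 0")
  stop_if_not(length(blink_dur_ms_range) == 2 && all(blink_dur_ms_range > 0),
              "invalid blink_dur_ms_range")
  stop_if_not(is_fraction(gaze_excursion_prob), "gaze_excursion_prob must lie in [0, 1]")
  stop_if_not(is_fraction(missing_trial_prob), "missing_trial_prob must lie in [0, 1]")
  stop_if_not(is_fraction(reliability_target) && reliability_target > 0,
              "reliability_target must lie in (0, 1]")
  stop_if_not(is_fraction(symptom_reliability), "symptom_reliability must lie in [0, 1]")
  stop_if_not(all(c("reward", "neutral", "control") %in% names(base_slopes)),
              "base_slopes must name reward/neutral/control")
  stop_if_not(all(c("reward", "neutral", "control") %in% names(trait_gains)),
              "trait_gains must name reward/neutral/control")

  if (is.null(trial_noise_sd)) {
    # Spearman-Brown for a 5-trial half: split-half r = v / (v + 2 s^2 / h)
    # with v the between-participant variance of the differential slope and
    # h = n_trials_per_condition / 2 trials per half.
    v <- (trait_gains[["reward"]] - trait_gains[["control"]])^2
    h <- n_trials_per_condition / 2
    trial_noise_sd <- sqrt((h / 2) * v *
                             (1 - reliability_target) / reliability_target)
  }
  stop_if_not(trial_noise_sd >= 0, "trial_noise_sd must be >= 0")

  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d participants (%.0f%% depressed), true latent rho %.2f\n",
              x$n_participants, 100 * x$prop_depressed, x$true_rho))
  cat(sprintf("  %d trials/condition at %g Hz; anticipation %g s\n",
              x$n_trials_per_condition, x$sampling_rate, x$anticipation_s))
  cat(sprintf("  trial slope jitter %.4f /s (split-half target %.2f)\n",
              x$trial_noise_sd, x$reliability_target))
  invisible(x)
}

#' Pseudo-randomized balanced condition order
#'
#' Draws a balanced sequence (equal trial counts per condition) with no run of
#' three or more identical conditions, by rejection sampling of random
#' permutations. Deterministic given `seed`.
#'
#' @param n_trials Total number of trials; must be divisible by `n_conditions`.
#' @param n_conditions Number of distinct conditions (labels are taken from
#'   `labels`).
#' @param seed Integer seed.
#' @param labels Condition labels; defaults to reward/neutral/control for
#'   three conditions.
#' @return Character vector of length `n_trials`.
#' @export
simulate_condition_order <- function(n_trials, n_conditions, seed,
                                     labels = NULL) {
  stop_if_not(is_count(n_trials) && is_count(n_conditions),
              "n_trials and n_conditions must be counts")
  stop_if_not(n_trials %% n_conditions == 0,
              "n_trials (%d) must be divisible by n_conditions (%d)",
              n_trials, n_conditions)
  per <- n_trials %/% n_conditions
  if (n_conditions == 1 && per >= 3)
    stop("impossible constraint: a single condition cannot avoid runs of 3",
         call. = FALSE)
  if (is.null(labels)) {
    labels <- if (n_conditions == 3) c("reward", "neutral", "control")
    else paste0("cond", seq_len(n_conditions))
  }
  stop_if_not(length(labels) == n_conditions, "need one label per condition")
  base <- rep(labels, each = per)
  ord <- with_seed(seed, {
    found <- NULL
    for (attempt in seq_len(10000L)) {
      cand <- sample(base)
      if (max(rle(cand)$lengths) < 3) { found <- cand; break }
    }
    found
  })
  if (is.null(ord))
    stop("could not find a balanced order without runs of 3", call. = FALSE)
  ord
}

# Discrete margin of the observed symptom count: P(0) = 1 - prop_depressed,
# counts 1..20 get geometrically decaying mass.
symptom_count_margin <- function(prop_depressed, decay = 12) {
  w <- exp(-(0:19) / decay)
  p <- c(1 - prop_depressed, prop_depressed * w / sum(w))
  names(p) <- 0:20
  p
}

# For Y = q(Phi(W)) with W ~ N(0,1) and a discrete margin p over values v:
# lambda = Cov(W, Y) / SD(Y), the attenuation of any Gaussian correlation
# under discretization. Exact via the normal density at the thresholds.
discretization_lambda <- function(p, values = as.numeric(names(p))) {
  cuts <- qnorm(cumsum(p))
  lo <- c(-Inf, cuts[-length(cuts)])
  hi <- cuts
  cov_wy <- sum(values * (dnorm(lo) - dnorm(hi)))
  ey <- sum(values * p)
  vy <- sum(values^2 * p) - ey^2
  if (vy <= 0) return(0)
  cov_wy / sqrt(vy)
}

# Map standard-normal scores to the discrete margin p (values 0..k).
discretize_gaussian <- function(w, p) {
  cuts <- qnorm(cumsum(p))
  findInterval(w, cuts[-length(cuts)], left.open = FALSE)
}

# Cohort-level layer of the generator: arousal traits, latent symptom
# burden, observed symptom counts (a calibrated noisy discretization of the
# burden) and BDI-II items. Draws from the caller's RNG stream; callers are
# responsible for seeding. Shared by simulate_study() and by feature-level
# property checks that do not need pupil traces.
simulate_cohort <- function(cfg) {
  margin <- symptom_count_margin(cfg$prop_depressed)
  lam <- discretization_lambda(margin)
  rho_a <- abs(cfg$true_rho)
  if (cfg$symptom_reliability > 0) {
    beta <- sqrt(cfg$symptom_reliability) / lam
    if (beta > 1) {
      warning(sprintf(
        paste("the discrete symptom margin can carry at most reliability %.2f",
              "(requested %.2f); using the maximal coupling"),
        lam^2, cfg$symptom_reliability), call. = FALSE)
      beta <- 1
    }
  } else beta <- 0

  item_p <- c(0.55, 0.25, 0.13, 0.07)
  c1 <- cfg$item_burden_loading
  loaded <- cfg$trait_loaded_items

  ids <- sprintf("P%03d", seq_len(cfg$n_participants))
  trait <- rnorm(cfg$n_participants)
  burden <- -rho_a * trait + sqrt(1 - rho_a^2) * rnorm(cfg$n_participants)
  w_obs <- beta * burden + sqrt(max(0, 1 - beta^2)) * rnorm(cfg$n_participants)
  count <- discretize_gaussian(w_obs, margin)
  group <- ifelse(count == 0, "HC", "MDD")

  # BDI items: all load on the burden; the anhedonia/energy items of
  # trait_loaded_items additionally on the (negative) arousal trait.
  items <- matrix(0L, cfg$n_participants, 21)
  for (j in 1:21) {
    c2 <- if (j %in% loaded) cfg$item_trait_loading else 0
    vs <- c1^2 + c2^2 + 2 * c1 * c2 * rho_a
    u <- c1 * burden + c2 * (-trait) +
      sqrt(max(0, 1 - vs)) * rnorm(cfg$n_participants)
    items[, j] <- discretize_gaussian(u, item_p)
  }
  colnames(items) <- sprintf("bdi_item_%02d", 1:21)

  list(ids = ids, trait = trait, burden = burden, count = count,
       group = group,
       clinical = data.frame(participant_id = ids, group = group,
                             symptom_count = count, items,
                             stringsAsFactors = FALSE))
}

# Expand each invalid run in `valid` by up to `pad_n` samples on each side
# (clipped at boundaries and at neighbouring runs), mirroring how blink
# interpolation widens the unusable region. Returns a logical "missing" mask.
pad_invalid_mask <- function(valid, pad_n) {
  miss <- !valid
  if (!any(miss) || pad_n <= 0) return(miss)
  runs <- logical_runs(miss)
  out <- miss
  n <- length(valid)
  for (i in seq_len(nrow(runs))) {
    a <- max(1L, runs$start[i] - pad_n)
    b <- min(n, runs$end[i] + pad_n)
    out[a:b] <- TRUE
  }
  out
}

#' Simulate a complete pupillometry study
#'
#' Generates, for every participant, a continuous 250 Hz pupil/gaze/validity
#' stream covering all trials, an event table with phase boundaries, a
#' clinical record (symptom count plus 21 BDI-II items), and a ground-truth
#' sidecar recording every planted quantity (arousal trait, per-trial ramp
#' slopes, blink/missing/gaze artifacts) so downstream quality control and
#' feature extraction can be tested exactly.
#'
#' The pupil trace within a trial is: tonic baseline (participant level plus a
#' per-trial offset, constant within the trial), a linear ramp over the
#' anticipation window with per-trial slope
#' `base_slope[cond] + trait_gain[cond] * trait + jitter`, a linear return to
#' baseline during the flash gap, an independent small ramp during feedback
#' (the consumption phase), and white measurement noise. Blinks are planted as
#' `valid = FALSE` runs with the pupil sample lost (`NA`).
#'
#' @param config A [sim_config()].
#' @return An object of class `pupil_study`: a list with `samples` (named list
#'   of per-participant sample tables), `events`, `clinical`, `truth` (a list
#'   with `participants` and `trials` tables) and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  stop_if_not(cfg$n_participants >= 2,
              "need at least 2 participants for any downstream correlation")

  fs <- cfg$sampling_rate
  dt <- 1 / fs
  n_trials <- 3L * cfg$n_trials_per_condition
  pad_n <- as.integer(round(0.1 * fs))  # 100 ms QC padding used by truth masks

  with_seed(cfg$seed, {
    cohort <- simulate_cohort(cfg)
    ids <- cohort$ids
    trait <- cohort$trait
    clinical <- cohort$clinical

    samples <- vector("list", cfg$n_participants)
    names(samples) <- ids
    events_list <- vector("list", cfg$n_participants)
    trials_list <- vector("list", cfg$n_participants)
    part_rows <- vector("list", cfg$n_participants)

    for (i in seq_len(cfg$n_participants)) {
      order_seed <- sample.int(2^31 - 10, 1)
      cond <- simulate_condition_order(n_trials, 3L, order_seed)

      # Grid-snapped trial timing.
      snap <- function(x) round(x * fs) / fs
      fix_dur <- snap(runif(n_trials, cfg$fixation_s_range[1], cfg$fixation_s_range[2]))
      fix_on <- numeric(n_trials)
      cue_on <- cue_off <- fb_on <- fb_off <- trial_end <- numeric(n_trials)
      t0 <- snap(1.0)  # lead-in
      for (k in seq_len(n_trials)) {
        fix_on[k] <- t0
        cue_on[k] <- fix_on[k] + fix_dur[k]
        cue_off[k] <- cue_on[k] + cfg$anticipation_s
        if (cond[k] == "control") {
          fb_on[k] <- NA_real_
          fb_off[k] <- NA_real_
          trial_end[k] <- cue_off[k] + cfg$flash_gap_s + cfg$iti_s
        } else {
          fb_on[k] <- cue_off[k] + cfg$flash_gap_s
          fb_off[k] <- fb_on[k] + cfg$feedback_s
          trial_end[k] <- fb_off[k] + cfg$iti_s
        }
        t0 <- trial_end[k]
      }
      session_end <- t0 + 1.0
      n_samp <- as.integer(round(session_end * fs))
      time_s <- (seq_len(n_samp) - 1L) * dt
      idx_of <- function(t) as.integer(floor(t * fs + 1e-6)) + 1L

      cond_trial_index <- stats::ave(seq_len(n_trials), cond, FUN = seq_along)
      slope <- cfg$base_slopes[cond] + cfg$trait_gains[cond] * trait[i] +
        rnorm(n_trials, 0, cfg$trial_noise_sd)
      cons_slope <- ifelse(cond == "control", NA_real_,
                           rnorm(n_trials, 0, cfg$trial_noise_sd))
      feedback_success <- ifelse(cond == "control", NA,
                                 runif(n_trials) < 0.5)
      base_off <- rnorm(n_trials, 0, cfg$baseline_step_sd)

      pupil <- rep(cfg$baseline_level, n_samp)
      for (k in seq_len(n_trials)) {
        i0 <- idx_of(fix_on[k]); i1 <- min(n_samp, idx_of(trial_end[k]) - 1L)
        pupil[i0:i1] <- pupil[i0:i1] + base_off[k]
        # anticipation ramp
        ia <- idx_of(cue_on[k]); ib <- idx_of(cue_off[k]) - 1L
        pupil[ia:ib] <- pupil[ia:ib] + slope[k] * (time_s[ia:ib] - cue_on[k])
        # linear return to baseline over the flash gap
        peak <- slope[k] * cfg$anticipation_s
        ig0 <- idx_of(cue_off[k])
        ig1 <- min(n_samp, idx_of(cue_off[k] + cfg$flash_gap_s) - 1L)
        pupil[ig0:ig1] <- pupil[ig0:ig1] +
          peak * (1 - (time_s[ig0:ig1] - cue_off[k]) / cfg$flash_gap_s)
        if (cond[k] != "control") {
          # consumption-phase ramp, independent of the trait
          if0 <- idx_of(fb_on[k]); if1 <- min(n_samp, idx_of(fb_off[k]) - 1L)
          pupil[if0:if1] <- pupil[if0:if1] +
            cons_slope[k] * (time_s[if0:if1] - fb_on[k])
          cpeak <- cons_slope[k] * cfg$feedback_s
          it0 <- idx_of(fb_off[k])
          it1 <- min(n_samp, idx_of(fb_off[k] + cfg$iti_s) - 1L)
          pupil[it0:it1] <- pupil[it0:it1] +
            cpeak * (1 - (time_s[it0:it1] - fb_off[k]) / cfg$iti_s)
        }
      }
      if (cfg$sample_noise_sd > 0)
        pupil <- pupil + rnorm(n_samp, 0, cfg$sample_noise_sd)

      # Blinks: Poisson process over the session.
      valid <- rep(TRUE, n_samp)
      n_blinks <- rpois(1, cfg$blink_rate * session_end / 60)
      if (n_blinks > 0) {
        b_on <- runif(n_blinks, 0, session_end - cfg$blink_dur_ms_range[2] / 1000)
        b_dur <- runif(n_blinks, cfg$blink_dur_ms_range[1],
                       cfg$blink_dur_ms_range[2]) / 1000
        for (b in seq_len(n_blinks)) {
          j0 <- idx_of(b_on[b]); j1 <- min(n_samp, idx_of(b_on[b] + b_dur[b]))
          valid[j0:j1] <- FALSE
        }
      }

      # Planted long missing runs (55% of the anticipation window).
      missing_planted <- runif(n_trials) < cfg$missing_trial_prob
      for (k in which(missing_planted)) {
        m0 <- cue_on[k] + 0.3
        m1 <- m0 + 0.55 * cfg$anticipation_s
        valid[idx_of(m0):(idx_of(m1) - 1L)] <- FALSE
      }

      # Gaze with planted excursions inside the anticipation window.
      gx <- cfg$gaze_center_px[1] + rnorm(n_samp, 0, cfg$gaze_noise_sd)
      gy <- cfg$gaze_center_px[2] + rnorm(n_samp, 0, cfg$gaze_noise_sd)
      excursion <- runif(n_trials) < cfg$gaze_excursion_prob
      excursion_s <- rep(0, n_trials)
      for (k in which(excursion)) {
        e_dur <- runif(1, cfg$gaze_excursion_s_range[1], cfg$gaze_excursion_s_range[2])
        e_dur <- min(e_dur, cfg$anticipation_s)
        e_on <- cue_on[k] + runif(1, 0, cfg$anticipation_s - e_dur)
        je <- idx_of(e_on):(idx_of(e_on + e_dur) - 1L)
        gx[je] <- gx[je] + sample(c(-1, 1), 1) * cfg$gaze_excursion_px
        excursion_s[k] <- sum(valid[je]) * dt  # valid-sample seconds planted outside
      }

      pupil[!valid] <- NA_real_

      # Truth-side missingness accounting (raw invalidity plus 100 ms padding,
      # the same convention the QC applies after blink interpolation).
      miss_pad <- pad_invalid_mask(valid, pad_n)
      trial_missing_frac <- vapply(seq_len(n_trials), function(k) {
        jj <- window_idx(time_s, cue_on[k], cue_off[k])
        mean(miss_pad[jj])
      }, numeric(1))

      samp <- data.frame(participant_id = ids[i], time_s = time_s,
                         pupil = pupil, gaze_x_px = gx, gaze_y_px = gy,
                         valid = valid, stringsAsFactors = FALSE)
      attr(samp, "sampling_rate_hz") <- fs
      samples[[i]] <- samp

      events_list[[i]] <- data.frame(
        participant_id = ids[i], trial_index = seq_len(n_trials),
        condition = cond, fixation_onset_s = fix_on, cue_onset_s = cue_on,
        cue_offset_s = cue_off, feedback_onset_s = fb_on,
        feedback_success = feedback_success, stringsAsFactors = FALSE)

      trials_list[[i]] <- data.frame(
        participant_id = ids[i], trial_index = seq_len(n_trials),
        condition = cond, cond_trial_index = cond_trial_index,
        slope = unname(slope), consumption_slope = cons_slope,
        baseline_offset = base_off, missing_planted = missing_planted,
        trial_missing_frac = trial_missing_frac,
        excursion = excursion, excursion_s = excursion_s,
        expected_drop_missing = trial_missing_frac > 0.5,
        expected_drop_gaze = excursion_s > 1.0,
        stringsAsFactors = FALSE)

      part_rows[[i]] <- data.frame(
        participant_id = ids[i], arousal_trait = trait[i],
        symptom_latent = cohort$burden[i],
        slope_reward = cfg$base_slopes[["reward"]] + cfg$trait_gains[["reward"]] * trait[i],
        slope_neutral = cfg$base_slopes[["neutral"]] + cfg$trait_gains[["neutral"]] * trait[i],
        slope_control = cfg$base_slopes[["control"]] + cfg$trait_gains[["control"]] * trait[i],
        symptom_count = cohort$count[i], group = cohort$group[i],
        session_missing_frac = mean(miss_pad),
        expected_session_drop = mean(miss_pad) > 0.15,
        session_sd_raw = sd(samp$pupil[!is.na(samp$pupil)]),
        stringsAsFactors = FALSE)
    }

    truth_part <- do.call(rbind, part_rows)
    truth_part$diff_slope <- truth_part$slope_reward - truth_part$slope_control
    rownames(truth_part) <- NULL

    study <- list(samples = samples,
                  events = do.call(rbind, events_list),
                  clinical = clinical,
                  truth = list(participants = truth_part,
                               trials = do.call(rbind, trials_list)),
                  config = cfg)
    rownames(study$events) <- NULL
    rownames(study$truth$trials) <- NULL
    class(study) <- "pupil_study"
    study
  })
}

#' @export
print.pupil_study <- function(x, ...) {
  n <- length(x$samples)
  cat("<pupil_study>\n")
  cat(sprintf("  %d participants, %d trials each, %g Hz\n",
              n, nrow(x$events) / n, x$config$sampling_rate))
  cat(sprintf("  groups: %d MDD / %d HC; true latent rho %.2f\n",
              sum(x$clinical$group == "MDD"), sum(x$clinical$group == "HC"),
              x$config$true_rho))
  invisible(x)
}
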