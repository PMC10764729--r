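#!/usr/bin/env Rscript

# Stage 4: the replication-style analyses. Latent correlation (with
# SD*sqrt(1-R) measurement uncertainty) between the differential dilation
# and symptom count within patients, plus the two control analyses: the
# conservative pupil reliability (0.70) and the reward-minus-neutral
# contrast that controls for the motor response. Each fit's posterior
# summary, directional Bayes factor and diagnostics go to TSV.

suppressMessages(library(pupilcorr))

args <- commandArgs(trailingOnly = TRUE)
dir <- if (length(args) >= 1) args[1] else "results/run"
seed <- if (length(args) >= 2) as.integer(args[2]) else 11

features <- read_features(file.path(dir, "features.tsv"))
clinical <- derive_clinical(read_clinical(file.path(dir, "clinical.tsv")))

fits <- list(
  replication = correlate_dilation_symptoms(
    features, clinical, seed = seed),
  low_reliability = correlate_dilation_symptoms(
    features, clinical, reliability_pupil = 0.70, seed = seed + 1),
  motor_control = correlate_dilation_symptoms(
    features, clinical, contrast = "reward_minus_neutral", seed = seed + 2),
  full_sample = correlate_dilation_symptoms(
    features, clinical, subset = "all", seed = seed + 3))

for (nm in names(fits)) {
  f <- fits[[nm]]
  write_posterior_summary(f, file.path(dir, sprintf("posterior_%s.tsv", nm)))
  s <- f$summary["rho", ]
  cat(sprintf("%-16s raw r %+.3f -> rho %+.3f [%.3f, %.3f], BF(-) %.4g%s\n",
              nm, attr(f, "analysis")$raw_pearson_r, s["mean"], s["q2.5"],
              s["q97.5"], f$bf_minus,
              if (f$bf_is_lower_bound) " (lower bound)" else ""))
}
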