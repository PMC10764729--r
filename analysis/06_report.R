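#!/usr/bin/env Rscript

# Stage 6: assemble the plain-text study report: QC summary, reliability,
# replication correlation, specificity screens and the HC-versus-depressed
# group comparisons.

suppressMessages(library(pupilcorr))

args <- commandArgs(trailingOnly = TRUE)
dir <- if (length(args) >= 1) args[1] else "results/run"
seed <- if (length(args) >= 2) as.integer(args[2]) else 21

samples <- read_samples(file.path(dir, "samples.tsv"))
events <- read_events(file.path(dir, "events.tsv"))
clinical <- read_clinical(file.path(dir, "clinical.tsv"))
cfg <- read_run_config(file.path(dir, "sim_config.txt"))

study <- list(samples = samples, events = events, clinical = clinical,
              config = list(n_trials_per_condition = 10, feedback_s = 1.5))
class(study) <- "pupil_study"

pipe <- analyze_study(study, chains = 4, iter = 2500, warmup = 600,
                      seed = seed, run_item_screen_stage = TRUE,
                      run_group_stage = TRUE)
lines <- pipeline_report(pipe)
writeLines(lines, file.path(dir, "report.txt"))
cat("report written to", file.path(dir, "report.txt"), "\n")
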