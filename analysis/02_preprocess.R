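#!/usr/bin/env Rscript

# Stage 2: apply the cleaning chain (blink interpolation, 200 ms sliding
# mean, session z-transform) and the QC rules (>50% missing trial, >15%
# missing session, 3.3 SD gaze window with the >1 s rule); write the QC
# report and the run manifest.

suppressMessages(library(pupilcorr))

args <- commandArgs(trailingOnly = TRUE)
dir <- if (length(args) >= 1) args[1] else "results/run"

samples <- read_samples(file.path(dir, "samples.tsv"))
events <- read_events(file.path(dir, "events.tsv"))
clean <- preprocess_study(samples, events)

qc <- merge(clean$qc_trials, clean$qc_sessions, by = "participant_id")
write.table(qc, file.path(dir, "qc_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_run_config(clean$manifest, file.path(dir, "manifest.txt"))
saveRDS(clean, file.path(dir, "clean.rds"))  # stage hand-off, not a deliverable

cat(sprintf("QC: %d/%d sessions kept; %d trials dropped (%d missing, %d gaze)\n",
            sum(!clean$qc_sessions$session_dropped), nrow(clean$qc_sessions),
            sum(clean$qc_trials$dropped),
            sum(clean$qc_trials$drop_reason == "missing"),
            sum(clean$qc_trials$drop_reason == "gaze")))
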