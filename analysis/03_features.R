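#!/usr/bin/env Rscript

# Stage 3: derivative-based dilation features per condition and phase,
# differential scores, split-half reliability, derived clinical records.

suppressMessages(library(pupilcorr))

args <- commandArgs(trailingOnly = TRUE)
dir <- if (length(args) >= 1) args[1] else "results/run"

clean <- readRDS(file.path(dir, "clean.rds"))
events <- read_events(file.path(dir, "events.tsv"))
clinical <- derive_clinical(read_clinical(file.path(dir, "clinical.tsv")))

features <- aggregate_features(clean, events)
trials <- trial_dilations(clean, events)
r_half <- split_half_reliability(trials)

write_features(features, file.path(dir, "features.tsv"))
write.table(trials, file.path(dir, "trial_dilations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(clinical, file.path(dir, "clinical_derived.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_run_config(list(split_half_reliability = r_half),
                 file.path(dir, "reliability.txt"))

cat(sprintf("features for %d participants; split-half reliability %.3f\n",
            nrow(features), r_half))
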