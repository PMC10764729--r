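#!/usr/bin/env Rscript

# Stage 5: item-level specificity. Default Bayes factors for the
# correlation of the differential dilation with each BDI-II item and the
# anhedonia score; rows with BF10 > 3 carry moderate evidence.

suppressMessages(library(pupilcorr))

args <- commandArgs(trailingOnly = TRUE)
dir <- if (length(args) >= 1) args[1] else "results/run"

features <- read_features(file.path(dir, "features.tsv"))
clinical <- derive_clinical(read_clinical(file.path(dir, "clinical.tsv")))

screen <- run_item_screen(features, clinical)
write.table(screen, file.path(dir, "item_screen.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

hits <- screen[which(screen$moderate_evidence), ]
cat(sprintf("%d of %d rows reach BF10 > 3\n", nrow(hits), nrow(screen)))
if (nrow(hits) > 0)
  cat(sprintf("  %-36s r = %+.2f  BF10 = %.3g\n", hits$label, hits$r,
              hits$bf10), sep = "")
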