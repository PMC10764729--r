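#!/usr/bin/env Rscript

# Stage 1: simulate a complete study at the default conditions and write the
# tabular contracts (samples/events/clinical plus ground-truth sidecars).
# Later stages read these files, so real data in the same formats can be
# substituted at any point.

suppressMessages(library(pupilcorr))

args <- commandArgs(trailingOnly = TRUE)
out_dir <- if (length(args) >= 1) args[1] else "results/run"
seed <- if (length(args) >= 2) as.integer(args[2]) else 1

cfg <- sim_config(n_participants = 70, prop_depressed = 40 / 70,
                  true_rho = -0.4, seed = seed)
study <- simulate_study(cfg)
write_study(study, out_dir)
write_run_config(list(seed = seed, n_participants = cfg$n_participants,
                      true_rho = cfg$true_rho,
                      sampling_rate = cfg$sampling_rate,
                      reliability_target = cfg$reliability_target,
                      symptom_reliability = cfg$symptom_reliability),
                 file.path(out_dir, "sim_config.txt"))

cat(sprintf("simulated %d participants (%d MDD / %d HC) into %s\n",
            cfg$n_participants, sum(study$clinical$group == "MDD"),
            sum(study$clinical$group == "HC"), out_dir))
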