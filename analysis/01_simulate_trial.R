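#!/usr/bin/env Rscript
# Simulate the default synthetic trial and persist it as plain-text CSV.
suppressPackageStartupMessages(library(rshte))

seed <- 20240101
out <- file.path("results", "trial")
dir.create("results", showWarnings = FALSE)

cfg <- synthetic_trial_config()   # 1,645 patients, 2:1, four outcomes
sim <- simulate_trial(cfg, seed = seed)
write_trial_dataset(sim$dataset, out)

sp <- split_train_validation(sim$dataset, 0.7, seed)
write.csv(sp$balance, file.path("results", "train_validation_balance.csv"),
          row.names = FALSE)
cat("dataset written to", out, "-", n_patients(sim$dataset), "patients\n")
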