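#!/usr/bin/env Rscript
# Performance evaluation of the selected EDSS response score: AD(q) curve,
# calibration by score quartile, bootstrap replicability (small run), and
# conditional permutation variable importance.
suppressPackageStartupMessages(library(rshte))

seed <- 20240101
ds <- read_trial_dataset(file.path("results", "trial"))
res <- select_response_score(ds, "EDSS", seed = seed)
valid <- res$split$validation
sc <- score_patients(res$selected, valid$baselines)

ad <- adq_curve(valid, "EDSS", sc)
write.csv(ad$curve, file.path("results", "adq_curve_edss.csv"),
          row.names = FALSE)
cat("AD(q) AUC:", round(ad$auc, 3), "\n")

cal <- calibration(valid, "EDSS", sc)
write.csv(cal, file.path("results", "calibration_edss.csv"),
          row.names = FALSE)

rep_ <- replicability(ds, "EDSS", n_replicates = 50, seed = seed)
cat("replicability pass rate (50 bootstrap resamples):",
    round(rep_$pass_rate, 3), "\n")

cl <- classify(sc, "overall_hr", reference = res$overall$hr)
vi <- variable_importance(valid$baselines,
                          setNames(cl$label, cl$patient_id), seed = seed)
write.csv(vi, file.path("results", "importance_edss.csv"),
          row.names = FALSE)
print(vi, digits = 3)
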