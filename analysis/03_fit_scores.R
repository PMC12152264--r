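#!/usr/bin/env Rscript
# Fit a clinical-practice response score per outcome on the training split
# of the persisted trial and tabulate coefficients next to the published
# models.
suppressPackageStartupMessages(library(rshte))

seed <- 20240101
ds <- read_trial_dataset(file.path("results", "trial"))
sp <- split_train_validation(ds, 0.7, seed)
terms <- variable_set("CLINICAL_PRACTICE")

rows <- lapply(c("EDSS", "9HPT", "T25FW", "SDMT"), function(oc) {
  fitted <- build_response_score(sp$train, oc, terms)
  pub <- published_score(oc)
  data.frame(outcome = oc,
             term = c("(intercept)", terms),
             fitted = c(fitted$intercept,
                        fitted$coefficients[terms]),
             published = c(pub$intercept,
                           ifelse(terms %in% names(pub$coefficients),
                                  pub$coefficients[terms], 0)),
             row.names = NULL)
})
tab <- do.call(rbind, rows)
write.csv(tab, file.path("results", "fitted_vs_published_scores.csv"),
          row.names = FALSE)
print(tab, digits = 3)
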