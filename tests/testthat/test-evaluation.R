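test_that("subgroup HRs are near 1 in a null world and flag degenerate groups", {
  cfg <- synthetic_trial_config(n_patients = 6000, world = "null",
                                event_frac = c(EDSS = 0.5, T25FW = 0.5,
                                               `9HPT` = 0.5, SDMT = 0.5),
                                censoring = list(admin_days = 720,
                                                 dropout_prob = 0))
  sim <- simulate_trial(cfg, seed = 19)
  ids <- sim$dataset$baselines$patient_id
  lab <- setNames(rep(c("A", "B"), length.out = length(ids)), ids)
  tab <- subgroup_hr(sim$dataset, "EDSS", lab)
  expect_equal(tab$group, c("A", "B"))
  expect_true(all(tab$evaluable))
  expect_true(all(abs(tab$hr - 1) < 0.15))
  expect_true(all(tab$ci_low < 1 & tab$ci_high > 1))

  # a one-patient subgroup has a single arm: not evaluable, still reported
  lab1 <- setNames(c("solo", rep("rest", length(ids) - 1)), ids)
  tab1 <- subgroup_hr(sim$dataset, "EDSS", lab1)
  expect_false(tab1$evaluable[tab1$group == "solo"])
  expect_true(is.na(tab1$hr[tab1$group == "solo"]))
})

test_that("subgroup CIs achieve roughly nominal coverage in a uniform world", {
  hit <- 0L
  for (i in 1:60) {
    cfg <- synthetic_trial_config(n_patients = 600, world = "average_only",
                                  overall_hr = 0.75)
    sim <- simulate_trial(cfg, seed = 1000 + i)
    ids <- sim$dataset$baselines$patient_id
    lab <- setNames(rep("all", length(ids)), ids)
    tab <- subgroup_hr(sim$dataset, "SDMT", lab)
    if (tab$ci_low <= 0.75 && 0.75 <= tab$ci_high) hit <- hit + 1L
  }
  expect_gte(hit / 60, 0.87)
  expect_lte(hit / 60, 1)
})

test_that("interaction test returns NA on degenerate input and detects planted HTE", {
  cfg <- synthetic_trial_config(n_patients = 1200)
  sim <- simulate_trial(cfg, seed = 42)
  ids <- sim$dataset$baselines$patient_id
  expect_true(is.na(interaction_test(sim$dataset, "EDSS",
                                     setNames(rep(1, length(ids)), ids))))

  hte <- list(EDSS = list(intercept = log(0.75) + 0.8 * 5.7,
                          coef = c(edss = -0.8)))
  cfg2 <- synthetic_trial_config(n_patients = 5000, hte = hte)
  sim2 <- simulate_trial(cfg2, seed = 43)
  z <- setNames(sim2$dataset$baselines$edss,
                sim2$dataset$baselines$patient_id)
  p <- interaction_test(sim2$dataset, "EDSS", z)
  expect_lt(p, 0.01)
})

test_that("AD(q) ends at the overall HR and is near-flat without heterogeneity", {
  cfg <- synthetic_trial_config(n_patients = 8000, world = "average_only",
                                overall_hr = 0.75)
  sim <- simulate_trial(cfg, seed = 27)
  rs <- published_score("EDSS")
  sc <- score_patients(rs, sim$dataset$baselines)
  ad <- adq_curve(sim$dataset, "EDSS", sc)
  df <- rshte:::outcome_frame(sim$dataset, "EDSS")
  overall <- rshte:::.cox_hr_ci(df$time, df$event, df$treat)$hr
  expect_equal(ad$curve$hr[ad$curve$q == 1], overall, tolerance = 1e-10)
  expect_lt(abs(ad$auc - overall), 0.05)
  expect_error(adq_curve(sim$dataset, "EDSS", sc, grid = c(0.2, 0.5)),
               "q = 1")
})

test_that("AD(q) dips below the overall HR under true heterogeneity", {
  hte <- list(EDSS = list(intercept = log(0.75) + 0.7 * 5.7,
                          coef = c(edss = -0.7)))
  cfg <- synthetic_trial_config(n_patients = 8000, hte = hte)
  sim <- simulate_trial(cfg, seed = 29)
  sc <- true_response_score(sim$truth, sim$dataset$baselines, "EDSS")
  ad <- adq_curve(sim$dataset, "EDSS", sc)
  overall <- ad$curve$hr[ad$curve$q == 1]
  expect_lt(ad$curve$hr[ad$curve$q == 0.1], overall)
  expect_lt(ad$auc, overall)
})

test_that("calibration bins are monotone in predicted score and handle constants", {
  # continuous (age-driven) score so all four quartile bins are populated
  hte <- list(EDSS = list(intercept = log(0.75) + 0.025 * 48,
                          coef = c(age = -0.025)))
  cfg <- synthetic_trial_config(n_patients = 10000, hte = hte)
  sim <- simulate_trial(cfg, seed = 33)
  sc <- true_response_score(sim$truth, sim$dataset$baselines, "EDSS")
  cal <- calibration(sim$dataset, "EDSS", sc)
  expect_equal(nrow(cal), 4)
  expect_true(all(cal$evaluable))
  expect_true(all(diff(cal$predicted_log_hr) >= 0))
  expect_equal(sum(cal$n), n_patients(sim$dataset))
  # observed effect tracks the prediction: extreme bins ordered, and the
  # predicted value falls in the observed CI for most bins
  expect_lt(cal$observed_log_hr[1], cal$observed_log_hr[4])
  covered <- sum(cal$ci_low <= cal$predicted_log_hr &
                   cal$predicted_log_hr <= cal$ci_high)
  expect_gte(covered, 3)

  # heavily tied discrete scores collapse bins; empties are flagged and kept
  hte2 <- list(EDSS = list(intercept = log(0.75) + 0.7 * 5.7,
                           coef = c(edss = -0.7)))
  cfg2 <- synthetic_trial_config(n_patients = 4000, hte = hte2)
  sim2 <- simulate_trial(cfg2, seed = 34)
  sc2 <- true_response_score(sim2$truth, sim2$dataset$baselines, "EDSS")
  cal2 <- calibration(sim2$dataset, "EDSS", sc2)
  expect_equal(nrow(cal2), 4)
  expect_true(any(!cal2$evaluable) || all(cal2$n > 0))
  expect_equal(sum(cal2$n), n_patients(sim2$dataset))

  # constant scores collapse to a single bin without error
  const <- setNames(rep(-0.3, n_patients(sim2$dataset)),
                    sim2$dataset$baselines$patient_id)
  calc <- calibration(sim2$dataset, "EDSS", const)
  expect_equal(calc$n[1], n_patients(sim2$dataset))
  expect_true(all(calc$n[-1] == 0))
})

test_that("replicability is a valid fraction, deterministic, and ordered by signal", {
  cfg <- synthetic_trial_config(n_patients = 1200, world = "null")
  sim <- simulate_trial(cfg, seed = 61)
  r1 <- replicability(sim$dataset, "EDSS", variables = c("edss", "age"),
                      n_replicates = 6, seed = 5)
  expect_s3_class(r1, "replicability_result")
  expect_gte(r1$pass_rate, 0)
  expect_lte(r1$pass_rate, 1)
  r1b <- replicability(sim$dataset, "EDSS", variables = c("edss", "age"),
                       n_replicates = 6, seed = 5)
  expect_identical(r1$log, r1b$log)

  hte <- list(EDSS = list(intercept = log(0.75) + 0.8 * 5.7,
                          coef = c(edss = -0.8)))
  cfg2 <- synthetic_trial_config(n_patients = 3000, hte = hte)
  sim2 <- simulate_trial(cfg2, seed = 62)
  r2 <- replicability(sim2$dataset, "EDSS", variables = c("edss", "age"),
                      n_replicates = 6, seed = 5)
  expect_gte(r2$pass_rate, r1$pass_rate)
})

test_that("Kaplan-Meier summaries match the product-limit definition", {
  cfg <- synthetic_trial_config(n_patients = 300)
  sim <- simulate_trial(cfg, seed = 71)
  km <- km_summary(sim$dataset, "EDSS")
  expect_setequal(unique(km$arm), c("treatment", "control"))
  expect_true(all(km$surv >= 0 & km$surv <= 1))
  for (a in unique(km$arm)) {
    s <- km$surv[km$arm == a]
    expect_true(all(diff(s) <= 1e-12))
  }
  # with no censoring, S(t) = 1 - ECDF of event times (checked by hand)
  df <- rshte:::outcome_frame(sim$dataset, "EDSS")
  sel <- df$treat == 1
  t_all <- df$time[sel]
  ev <- rep(1L, length(t_all))
  fit <- survival::survfit(survival::Surv(t_all, ev) ~ 1)
  expect_equal(fit$surv, 1 - ecdf(t_all)(fit$time), tolerance = 1e-12)

  # a dataset with zero events keeps survival at 1
  cfg0 <- synthetic_trial_config(n_patients = 40,
                                 censoring = list(admin_days = 0,
                                                  dropout_prob = 0))
  sim0 <- simulate_trial(cfg0, seed = 1)
  km0 <- km_summary(sim0$dataset, "EDSS")
  expect_true(all(km0$surv == 1))
})

test_that("conditional permutation importance isolates a planted driver", {
  set.seed(90)
  n <- 800
  b <- data.frame(patient_id = sprintf("P%04d", 1:n),
                  arm = rep(c("treatment", "control"), length.out = n),
                  age = runif(n, 18, 60),
                  sex = sample(c("female", "male"), n, TRUE),
                  edss = sample(seq(3, 6.5, 0.5), n, TRUE),
                  relapses_2y = rpois(n, 0.7),
                  disease_duration = exp(runif(n, 0, 3)),
                  stringsAsFactors = FALSE)
  lab <- setNames(ifelse(b$edss > median(b$edss), "responder",
                         "non_responder"), b$patient_id)
  vi <- variable_importance(b, lab, variables = variable_set("CLINICAL_PRACTICE"),
                            num_trees = 300, n_perm = 3, seed = 7)
  expect_equal(vi$variable[1], "edss")
  expect_equal(vi$pct_vi[1], 100)
  expect_true(all(vi$pct_vi[vi$variable != "edss"] < 30))

  # labels independent of covariates carry no importance
  set.seed(91)
  lab0 <- setNames(sample(c("responder", "non_responder"), n, TRUE),
                   b$patient_id)
  vi0 <- variable_importance(b, lab0, variables = c("age", "edss"),
                             num_trees = 300, n_perm = 3, seed = 7)
  expect_true(all(abs(vi0$vi) < 0.02))

  lab_one <- setNames(rep("responder", n), b$patient_id)
  expect_error(variable_importance(b, lab_one, variables = c("age", "edss")),
               "single class")
})
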