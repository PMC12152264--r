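test_that("published score fixtures reproduce the worked patients", {
  m <- published_score("T25FW")
  p <- worked_patients()
  sc <- score_patients(m, p)
  expect_equal(round_half_up(unname(sc["patient_1"])), -0.24)
  expect_equal(round_half_up(unname(sc["patient_3"])), -0.66)
  m9 <- published_score("9HPT")
  expect_equal(unname(score_patients(m9, p)["patient_3"]), -0.39 + 0.005 * 30)
  # score of an all-zero transformed profile equals the intercept
  zero <- data.frame(patient_id = "Z", arm = "treatment", age = 0,
                     sex = "female", edss = 0, relapses_2y = 0,
                     disease_duration = 1)
  expect_equal(unname(score_patients(m, zero)), m$intercept)
  # missing required variable named in the error
  expect_error(score_patients(m, p[, setdiff(names(p), "edss")]), "edss")
})

test_that("scoring is affine in the transformed covariates", {
  m <- published_score("SDMT")
  p <- worked_patients()
  sc <- score_patients(m, p)
  X <- covariate_matrix(p, names(m$coefficients))
  diff12 <- drop((X[1, ] - X[2, ]) %*% m$coefficients)
  expect_equal(unname(sc[1] - sc[2]), diff12)
})

test_that("arm-wise Cox fits recover known prognostic coefficients", {
  cfg <- synthetic_trial_config(
    n_patients = 7500, world = "null",
    prognostic_coef = c(edss = 0.5),
    event_frac = c(EDSS = 0.6, T25FW = 0.6, `9HPT` = 0.6, SDMT = 0.6),
    censoring = list(admin_days = 720, dropout_prob = 0))
  sim <- simulate_trial(cfg, seed = 14)
  ft <- fit_arm_model(sim$dataset, "treatment", "EDSS", c("edss", "age"))
  expect_true(ft$converged)
  expect_lt(abs(ft$coefficients[["edss"]] - 0.5), 0.07)
  # a covariate independent of the hazard estimates near zero
  expect_lt(abs(ft$coefficients[["age"]]), 0.05)

  # zero events in an arm is a precondition failure
  cfg0 <- synthetic_trial_config(n_patients = 40,
                                 censoring = list(admin_days = 0,
                                                  dropout_prob = 0))
  sim0 <- simulate_trial(cfg0, seed = 1)
  expect_error(fit_arm_model(sim0$dataset, "control", "EDSS", "edss"),
               "no events")
})

test_that("a world without heterogeneity yields a flat score at the overall effect", {
  cfg <- synthetic_trial_config(
    n_patients = 10000, world = "average_only", overall_hr = 0.75,
    event_frac = c(EDSS = 0.6, T25FW = 0.6, `9HPT` = 0.6, SDMT = 0.6),
    censoring = list(admin_days = 720, dropout_prob = 0))
  sim <- simulate_trial(cfg, seed = 6)
  terms <- variable_set("CLINICAL_PRACTICE")
  rs <- build_response_score(sim$dataset, "EDSS", terms)
  expect_true(all(abs(rs$coefficients) < 0.07))
  # the score at the reference covariate profile recovers the overall log HR
  ref <- reference_profile(sim$dataset$baselines, terms)
  at_ref <- rs$intercept + sum(ref * rs$coefficients)
  expect_lt(abs(at_ref - log(0.75)), 0.07)
})

test_that("empty covariate subsets reduce to the overall treatment effect", {
  cfg <- synthetic_trial_config(n_patients = 2000, world = "average_only",
                                overall_hr = 0.7)
  sim <- simulate_trial(cfg, seed = 10)
  rs <- build_response_score(sim$dataset, "SDMT", character(0))
  df <- rshte:::outcome_frame(sim$dataset, "SDMT")
  fit <- survival::coxph(survival::Surv(df$time, df$event) ~ df$treat,
                         ties = "efron")
  expect_equal(rs$intercept, unname(coef(fit)), tolerance = 1e-8)
  expect_length(rs$coefficients, 0)
})

test_that("swapping arms negates the fitted score", {
  cfg <- synthetic_trial_config(n_patients = 1500)
  sim <- simulate_trial(cfg, seed = 17)
  terms <- c("age", "edss")
  rs <- build_response_score(sim$dataset, "EDSS", terms)
  swapped <- sim$dataset
  swapped$baselines$arm <- ifelse(swapped$baselines$arm == "treatment",
                                  "control", "treatment")
  rs2 <- build_response_score(swapped, "EDSS", terms)
  expect_equal(rs2$coefficients, -rs$coefficients, tolerance = 1e-6)
  expect_equal(rs2$intercept, -rs$intercept, tolerance = 1e-6)
})

test_that("two-fit and pooled constructions agree asymptotically", {
  cfg <- synthetic_trial_config(n_patients = 12000, world = "table2",
                                censoring = list(admin_days = 720,
                                                 dropout_prob = 0))
  sim <- simulate_trial(cfg, seed = 23)
  terms <- c("age", "edss")
  a <- build_response_score(sim$dataset, "EDSS", terms, method = "two_fit")
  b <- build_response_score(sim$dataset, "EDSS", terms, method = "pooled")
  expect_equal(a$coefficients, b$coefficients, tolerance = 0.05)
  expect_identical(a$intercept, b$intercept)  # shared pooled intercept
})

test_that("classification thresholds and tie handling are inclusive", {
  sc <- setNames(c(-1, -1, -1, -1), paste0("P", 1:4))
  cl <- classify(sc, "train_quartile", reference = sc)
  expect_true(all(cl$label == "responder"))  # score == threshold at ties

  sc2 <- setNames(seq(-2, 1, length.out = 100), sprintf("Q%03d", 1:100))
  cl2 <- classify(sc2, "train_quartile", reference = sc2)
  frac <- mean(cl2$label == "responder")
  expect_gte(frac, 0.25)
  expect_lte(frac, 0.25 + 1 / 100 + 1e-9)

  cl3 <- classify(sc2, "overall_hr", reference = 0.8)
  expect_equal(unique(cl3$threshold), log(0.8))
  expect_equal(cl3$hr, exp(cl3$score))
  expect_error(classify(sc2, "overall_hr", reference = -1), "positive")
})
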