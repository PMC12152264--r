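test_that("baseline tables round-trip with missingness preserved and bad input rejected", {
  b <- make_baselines(3, with_gfap = TRUE)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(b, f, row.names = FALSE, na = "NA")
  got <- read_baseline_table(f)
  expect_equal(nrow(got), 3)
  expect_false(anyNA(got))
  expect_equal(got$age, b$age)

  b2 <- b; b2$gfap[2] <- NA
  write.csv(b2, f, row.names = FALSE, na = "NA")
  got2 <- read_baseline_table(f)
  expect_true(is.na(got2$gfap[2]))
  expect_false(anyNA(got2$gfap[-2]))

  b3 <- b; b3$patient_id <- c("P1", "P1", "P3")
  write.csv(b3, f, row.names = FALSE, na = "NA")
  expect_error(read_baseline_table(f), "P1")

  b4 <- b; b4$arm[2] <- "armX"
  write.csv(b4, f, row.names = FALSE, na = "NA")
  expect_error(read_baseline_table(f), "row 2")

  b5 <- b; b5$age <- as.character(b5$age); b5$age[3] <- "forty"
  write.csv(b5, f, row.names = FALSE, na = "NA")
  expect_error(read_baseline_table(f), "age")

  # custom arm labels map through
  b6 <- b; b6$arm <- rep(c("siponimod", "placebo"), length.out = 3)
  write.csv(b6, f, row.names = FALSE, na = "NA")
  got6 <- read_baseline_table(f, arm_map = c(siponimod = "treatment",
                                             placebo = "control"))
  expect_equal(got6$arm, rep(c("treatment", "control"), length.out = 3))
})

test_that("dataset writer reproduces every numeric value exactly on re-read", {
  cfg <- synthetic_trial_config(n_patients = 40)
  sim <- simulate_trial(cfg, seed = 5)
  dir <- withr::local_tempdir()
  write_trial_dataset(sim$dataset, dir)
  back <- read_trial_dataset(dir)
  num <- vapply(sim$dataset$baselines, is.numeric, TRUE)
  for (v in names(num)[num])
    expect_equal(back$baselines[[v]], as.numeric(sim$dataset$baselines[[v]]))
  expect_identical(back$events$time_days,
                   as.numeric(sim$dataset$events$time_days))
  expect_equal(back$events$event, sim$dataset$events$event)
})

test_that("70:30 split reproduces the trial allocation and partitions the cohort", {
  b <- data.frame(patient_id = sprintf("P%04d", 1:1645),
                  arm = rep(c("treatment", "treatment", "control"),
                            length.out = 1645),
                  age = runif(1645, 18, 60), sex = "female", edss = 4,
                  relapses_2y = 1, disease_duration = 5,
                  stringsAsFactors = FALSE)
  ds <- trial_dataset(b)
  sp <- split_train_validation(ds, 0.7, seed = 11)
  expect_equal(n_patients(sp$train), 1152)
  expect_equal(n_patients(sp$validation), 493)
  expect_length(intersect(sp$train$baselines$patient_id,
                          sp$validation$baselines$patient_id), 0)
  expect_setequal(c(sp$train$baselines$patient_id,
                    sp$validation$baselines$patient_id), b$patient_id)

  sp2 <- split_train_validation(ds, 0.7, seed = 11)
  expect_identical(sort(sp$train$baselines$patient_id),
                   sort(sp2$train$baselines$patient_id))

  small <- trial_dataset(b[1:10, ])
  expect_equal(n_patients(split_train_validation(small, 0.5, 3)$train), 5)
  expect_error(split_train_validation(ds, 1.2), "fraction")
  expect_true(all(c("variable", "d", "flag") %in% names(sp$balance)))
})

test_that("Cohen's d follows the pooled-SD definition, is antisymmetric and flags |d| > 0.10", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  expect_equal(cohens_d(x, x, "continuous")$d, 0)
  expect_false(cohens_d(x, x, "continuous")$flag)

  # proportion oracle: direct evaluation of the stated formula
  a <- c(0, 0, 1, 1); b <- c(1, 1, 1, 1)
  pbar <- 6 / 8
  d_hand <- (0.5 - 1) / sqrt(pbar * (1 - pbar))
  got <- cohens_d(a, b, "proportion")
  expect_equal(got$d, d_hand)
  expect_true(got$flag)

  y <- x + 1.7
  expect_equal(cohens_d(x, y, "continuous")$d,
               -cohens_d(y, x, "continuous")$d)
  expect_error(cohens_d(c(1, 1), c(2, 2), "continuous"), "degenerate")
})

test_that("chained-equation imputation preserves observed cells and recovers a deterministic relation", {
  b <- make_baselines(60)
  b$age <- runif(60, 20, 60)
  b$t25fw_base <- 2 * b$age   # exact linear relation
  b$hpt9_base <- runif(60, 20, 40)
  b$sdmt_base <- round(runif(60, 20, 70))
  ds <- trial_dataset(b)

  # fully observed input: m identical copies
  done <- mice_impute(ds, m = 3, seed = 2)
  expect_length(done, 3)
  expect_identical(done[[1]]$baselines, b)

  b2 <- b; b2$t25fw_base[7] <- NA; b2$hpt9_base[13] <- NA
  ds2 <- trial_dataset(b2)
  done2 <- mice_impute(ds2, m = 4, seed = 9)
  for (d in done2) {
    expect_false(anyNA(d$baselines))
    # observed cells untouched
    expect_identical(d$baselines$t25fw_base[-7], b2$t25fw_base[-7])
    expect_identical(d$baselines$hpt9_base[-13], b2$hpt9_base[-13])
    # the exact relation t25fw = 2*age drives the imputed cell
    expect_lt(abs(d$baselines$t25fw_base[7] - 2 * b2$age[7]), 0.2)
  }

  b3 <- b; b3$hpt9_base <- NA
  expect_error(mice_impute(trial_dataset(b3), m = 2, seed = 1), "hpt9_base")
})

test_that("Rubin pooling combines within- and between-imputation variance", {
  est <- c(1.0, 1.2, 0.8)
  v <- c(0.04, 0.04, 0.04)
  p <- pool_rubin(est, v)
  expect_equal(unname(p$estimate), 1.0)
  expect_equal(unname(p$variance), 0.04 + (1 + 1 / 3) * var(est))
})
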