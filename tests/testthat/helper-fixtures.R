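# shared fixtures built in code

# small baseline table with optional missingness
make_baselines <- function(n = 6, with_gfap = FALSE) {
  b <- data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    arm = rep(c("treatment", "control"), length.out = n),
    age = seq(30, 59, length.out = n),
    sex = rep(c("female", "male"), length.out = n),
    edss = rep(c(3, 4.5, 6), length.out = n),
    relapses_2y = rep(0:2, length.out = n),
    disease_duration = seq(2, 12, length.out = n),
    stringsAsFactors = FALSE)
  if (with_gfap) b$gfap <- seq(50, 150, length.out = n)
  b
}

# one patient's visits as a data frame
visits_df <- function(days, ..., pid = "P1") {
  data.frame(patient_id = pid, day = days, ..., stringsAsFactors = FALSE)
}

# normalized event table for round-trip comparisons
event_key <- function(e) {
  e <- as.data.frame(e)[c("patient_id", "outcome", "time_days", "event")]
  e$time_days <- as.numeric(e$time_days)
  e$event <- as.integer(e$event)
  e <- e[order(e$patient_id, e$outcome), ]
  rownames(e) <- NULL
  e
}

# the worked-example patient profiles
worked_patients <- function() {
  data.frame(
    patient_id = c("patient_1", "patient_2", "patient_3"),
    arm = "treatment",
    age = c(55, 45, 30), sex = c("female", "male", "female"),
    edss = c(3, 5, 2), relapses_2y = c(5, 1, 6),
    disease_duration = c(3, 4, 2), stringsAsFactors = FALSE)
}

# wide-spread generator settings used for parameter-recovery checks
recovery_config <- function(n) {
  synthetic_trial_config(
    n_patients = n, world = "table2",
    baseline_model = list(dd_meanlog = log(6), dd_sdlog = 1.4,
                          dd_range = c(0.1, 45), relapse_rate = 1.0),
    event_frac = c(EDSS = 0.85, T25FW = 0.85, `9HPT` = 0.85, SDMT = 0.85),
    censoring = list(admin_days = 1080, dropout_prob = 0))
}

# reference covariate profile of a baseline table on the transformed scale
reference_profile <- function(baselines, terms) {
  colMeans(covariate_matrix(baselines, terms))
}
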