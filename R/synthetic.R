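#' Synthetic two-arm progression trial configuration
#'
#' Defines a generative world for a 2:1 randomized secondary-progressive MS
#' trial: baseline covariate marginals matching the trial inclusion criteria
#' (age 18-60, EDSS 3.0-6.5), and per-outcome exponential proportional-hazards
#' event models with arm-specific coefficients. The treatment-minus-control
#' coefficient difference *is* the ground-truth response score, so every
#' downstream estimator can be checked against known truth.
#'
#' Worlds:
#' * `"table2"` (default): the treatment-arm log-hazard differs from control
#'   by the published clinical-practice score formulas, so the true response
#'   score of each outcome equals the published fixture.
#' * `"null"`: both arms share one model; all true score coefficients and
#'   intercepts are zero.
#' * `"average_only"`: a uniform treatment effect `overall_hr` with no
#'   heterogeneity (true score = constant log `overall_hr`).
#' * custom: pass `hte`, a named list per outcome with `intercept` and named
#'   `coef` on the transformed-covariate scale.
#'
#' @param n_patients cohort size (default 1645).
#' @param allocation treatment:control ratio (default `c(2, 1)`).
#' @param world one of `"table2"`, `"null"`, `"average_only"`.
#' @param overall_hr marginal treatment hazard ratio for
#'   `world = "average_only"` (default 0.75).
#' @param hte optional custom ground truth overriding `world` (see above).
#' @param outcomes outcomes to simulate.
#' @param baseline_model list of marginal-distribution settings; see defaults
#'   in the function signature.
#' @param prognostic_coef named control-arm log-hazard coefficients on
#'   transformed covariates.
#' @param event_frac named target control-arm event fraction per outcome over
#'   the administrative window (sets the baseline hazard scale).
#' @param censoring list with `admin_days` and `dropout_prob` (uniform
#'   dropout over the administrative window for that fraction of patients).
#' @param visit_schedule list with `spacing_days` and `horizon_days`.
#' @param trajectory_noise named per-score measurement SD for simulated
#'   visit trajectories (default all 0).
#' @param confirm_windows named confirmation windows (days) per outcome.
#' @param frailty_sd SD of an optional shared patient-level log-normal
#'   frailty inducing extra correlation between outcomes (default 0 = off).
#' @return list of class `synthetic_trial_config`.
#' @export
synthetic_trial_config <- function(
    n_patients = 1645,
    allocation = c(2, 1),
    world = c("table2", "null", "average_only"),
    overall_hr = 0.75,
    hte = NULL,
    outcomes = c("EDSS", "T25FW", "9HPT", "SDMT"),
    baseline_model = list(),
    prognostic_coef = c(age = 0.01, male = 0.05, edss = 0.20,
                        relapses_2y = 0.10, log10_disease_duration = 0.10),
    event_frac = c(EDSS = 0.30, T25FW = 0.35, `9HPT` = 0.25, SDMT = 0.30),
    censoring = list(admin_days = 720, dropout_prob = 0.10),
    visit_schedule = list(spacing_days = 90, horizon_days = 720),
    trajectory_noise = c(edss = 0, t25fw = 0, hpt9 = 0, sdmt = 0),
    confirm_windows = c(EDSS = 84, T25FW = 84, `9HPT` = 84, SDMT = 168),
    frailty_sd = 0) {
  world <- match.arg(world)
  stopifnot(n_patients >= 2, all(allocation > 0))
  bm <- utils::modifyList(list(
    age_mean = 48, age_sd = 8, age_range = c(18, 60),
    edss_levels = seq(3.0, 6.5, by = 0.5),
    edss_probs = c(0.05, 0.06, 0.08, 0.10, 0.10, 0.10, 0.25, 0.26),
    female_prob = 0.60, relapse_rate = 0.7,
    dd_meanlog = log(12), dd_sdlog = 0.6, dd_range = c(0.5, 45),
    include_tiers = 2L), baseline_model)
  if (any(event_frac[outcomes] <= 0) || any(event_frac[outcomes] >= 1))
    stop("event_frac must be in (0, 1)")
  if (censoring$admin_days < 0) stop("admin_days must be non-negative")

  truth <- if (!is.null(hte)) {
    lapply(hte[outcomes], function(h)
      list(intercept = h$intercept %||% 0, coef = h$coef %||% numeric(0)))
  } else switch(world,
    null = stats::setNames(rep(list(list(intercept = 0,
                                         coef = numeric(0))),
                               length(outcomes)), outcomes),
    average_only = stats::setNames(rep(list(list(intercept = log(overall_hr),
                                                 coef = numeric(0))),
                                       length(outcomes)), outcomes),
    table2 = {
      tr <- lapply(outcomes, function(oc) {
        m <- published_score(oc)
        list(intercept = m$intercept, coef = m$coefficients)
      })
      stats::setNames(tr, outcomes)
    })
  names(truth) <- outcomes

  structure(list(n_patients = as.integer(n_patients),
                 allocation = allocation, world = world,
                 outcomes = outcomes, truth = truth,
                 baseline_model = bm, prognostic_coef = prognostic_coef,
                 event_frac = event_frac, censoring = censoring,
                 visit_schedule = visit_schedule,
                 trajectory_noise = trajectory_noise,
                 confirm_windows = confirm_windows,
                 frailty_sd = frailty_sd),
            class = "synthetic_trial_config")
}

# reference covariate values used to anchor the baseline hazard scale
.REF_COVARIATES <- c(age = 48, male = 0.4, edss = 5.7, relapses_2y = 0.7,
                     log10_disease_duration = 1.08)

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

.rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  p <- stats::runif(n, stats::plnorm(lo, meanlog, sdlog),
                    stats::plnorm(hi, meanlog, sdlog))
  stats::qlnorm(p, meanlog, sdlog)
}

#' Simulate baseline profiles
#'
#' Draws `n_patients` baseline profiles with arm assignment by the allocation
#' ratio (treatment count = allocation fraction times N, rounded half up,
#' then randomly permuted). All marginals respect their configured supports.
#'
#' @param config a `synthetic_trial_config`.
#' @param seed integer seed; generation is a pure function of
#'   (config, seed).
#' @return data frame of baseline profiles.
#' @export
simulate_baselines <- function(config, seed = 1L) {
  set.seed(as.integer(seed))
  n <- config$n_patients
  bm <- config$baseline_model
  n_treat <- as.integer(round_half_up(
    config$allocation[1] / sum(config$allocation) * n, 0))
  arm <- sample(c(rep("treatment", n_treat), rep("control", n - n_treat)))
  b <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    arm = arm,
    age = .rtrunc_norm(n, bm$age_mean, bm$age_sd,
                       bm$age_range[1], bm$age_range[2]),
    sex = ifelse(stats::runif(n) < bm$female_prob, "female", "male"),
    edss = sample(bm$edss_levels, n, replace = TRUE, prob = bm$edss_probs),
    relapses_2y = stats::rpois(n, bm$relapse_rate),
    disease_duration = .rtrunc_lnorm(n, bm$dd_meanlog, bm$dd_sdlog,
                                     bm$dd_range[1], bm$dd_range[2]),
    stringsAsFactors = FALSE)
  if (bm$include_tiers >= 2L) {
    b$t25fw_base <- .rtrunc_lnorm(n, log(9), 0.4, 3, 60)
    b$hpt9_base <- .rtrunc_lnorm(n, log(30), 0.3, 12, 120)
    b$sdmt_base <- pmin(110, pmax(10, round(stats::rnorm(n, 43, 13))))
  }
  if (bm$include_tiers >= 3L) {
    b$gd_count <- stats::rpois(n, 0.6)
    b$t2_volume <- .rtrunc_lnorm(n, log(10), 0.8, 0.5, 80)
  }
  if (bm$include_tiers >= 4L) {
    b$cgm_volume <- stats::rnorm(n, 620, 60)
    b$thalamus_volume <- stats::rnorm(n, 9.5, 1.2)
    b$gfap <- .rtrunc_lnorm(n, log(120), 0.5, 20, 1000)
    b$nfl <- .rtrunc_lnorm(n, log(30), 0.6, 3, 500)
  }
  b
}

# per-arm log-hazard model for one outcome
.arm_models <- function(config, outcome) {
  beta_c <- config$prognostic_coef
  rate0 <- -log(1 - config$event_frac[[outcome]]) /
    max(config$censoring$admin_days, 1)
  log_rate_c <- log(rate0) -
    sum(beta_c * .REF_COVARIATES[names(beta_c)], na.rm = TRUE)
  delta <- config$truth[[outcome]]
  terms_t <- union(names(beta_c), names(delta$coef))
  beta_t <- stats::setNames(rep(0, length(terms_t)), terms_t)
  beta_t[names(beta_c)] <- beta_c
  beta_t[names(delta$coef)] <- beta_t[names(delta$coef)] + delta$coef
  list(control = list(log_rate = log_rate_c, coef = beta_c),
       treatment = list(log_rate = log_rate_c + delta$intercept,
                        coef = beta_t))
}

#' Simulate event times under the configured proportional-hazards world
#'
#' Event times are drawn by inverse transform from the arm- and
#' covariate-specific exponential hazard; censoring is the minimum of the
#' administrative time and (for a `dropout_prob` fraction of patients) a
#' uniform dropout time shared across outcomes.
#'
#' @param baselines output of [simulate_baselines()].
#' @param config the matching `synthetic_trial_config`.
#' @param seed integer seed.
#' @return list with `events` (long event table), `truth` (per-outcome true
#'   score intercept and coefficients), and `followup` (per-patient censoring
#'   time in days).
#' @export
simulate_event_times <- function(baselines, config, seed = 1L) {
  set.seed(derive_seed(seed, 1L))
  n <- nrow(baselines)
  admin <- config$censoring$admin_days
  frail <- if (config$frailty_sd > 0)
    stats::rnorm(n, -config$frailty_sd^2 / 2, config$frailty_sd)
  else rep(0, n)
  dropout <- ifelse(stats::runif(n) < config$censoring$dropout_prob,
                    stats::runif(n, 0, admin), Inf)
  followup <- pmin(admin, dropout)
  rows <- lapply(config$outcomes, function(oc) {
    mods <- .arm_models(config, oc)
    terms <- names(mods$treatment$coef)
    X <- covariate_matrix(baselines, terms)
    treat <- baselines$arm == "treatment"
    lp <- ifelse(treat,
                 mods$treatment$log_rate +
                   drop(X %*% mods$treatment$coef[terms]),
                 mods$control$log_rate +
                   drop(X[, names(mods$control$coef), drop = FALSE] %*%
                          mods$control$coef))
    rate <- exp(lp + frail)
    tt <- stats::rexp(n, rate)
    ev <- tt <= followup
    data.frame(patient_id = baselines$patient_id, outcome = oc,
               time_days = ifelse(ev, tt, followup),
               event = as.integer(ev), stringsAsFactors = FALSE)
  })
  list(events = do.call(rbind, rows), truth = config$truth,
       followup = stats::setNames(followup, baselines$patient_id))
}

#' True response scores implied by a synthetic ground truth
#'
#' @param truth `truth` element returned by [simulate_event_times()] (or a
#'   `synthetic_trial_config$truth`).
#' @param baselines baseline table.
#' @param outcome outcome name.
#' @return numeric vector of true per-patient scores (log HR scale).
#' @export
true_response_score <- function(truth, baselines, outcome) {
  tr <- truth[[outcome]]
  s <- rep(tr$intercept, nrow(baselines))
  if (length(tr$coef)) {
    X <- covariate_matrix(baselines, names(tr$coef))
    s <- s + drop(X %*% tr$coef)
  }
  stats::setNames(s, baselines$patient_id)
}

#' Snap latent event times onto the visit grid
#'
#' Progression is only observable at scheduled visits, so a latent event at
#' time t is recorded at the first grid visit at or after t, and only if a
#' confirming visit at least the outcome's window later still falls inside
#' the patient's follow-up; otherwise the record becomes a censoring at the
#' patient's last attended visit. Censoring times are snapped down to the
#' last grid visit attended.
#'
#' @param events long event table from [simulate_event_times()].
#' @param followup named per-patient follow-up times (days).
#' @param config the `synthetic_trial_config` (visit schedule and windows).
#' @return event table on the visit grid.
#' @export
snap_events_to_grid <- function(events, followup, config) {
  sp <- config$visit_schedule$spacing_days
  horizon <- config$visit_schedule$horizon_days
  last_day <- pmin(sp * floor(followup / sp), sp * floor(horizon / sp))
  ld <- last_day[events$patient_id]
  win <- config$confirm_windows[events$outcome]
  snapped <- sp * ceiling(events$time_days / sp)
  confirm_day <- snapped + sp * ceiling(win / sp)
  ok <- events$event == 1L & confirm_day <= ld
  out <- events
  out$time_days <- ifelse(ok, snapped, ld)
  out$event <- as.integer(ok)
  out
}

#' Simulate visit-level score trajectories
#'
#' Builds per-visit EDSS, T25FW, 9HPT and SDMT scores on the configured grid
#' by threshold crossing: each score stays at its baseline value until the
#' outcome's (grid-aligned) event day, then crosses the progression threshold
#' and stays worsened. With `trajectory_noise = 0`, applying the
#' confirmed-progression rules to these visits reproduces the grid-aligned
#' event table exactly; positive noise corrupts the derived events (by
#' design). Noise draws are standard normals scaled by the configured SD, so
#' fixed-seed runs at increasing SD corrupt monotonically.
#'
#' @param baselines baseline table (tier-2 fields required).
#' @param events *grid-aligned* event table (see [snap_events_to_grid()]).
#' @param followup named per-patient follow-up times (days).
#' @param config the `synthetic_trial_config`.
#' @param seed integer seed.
#' @return data frame of visit records (`patient_id`, `day`, `edss`,
#'   `t25fw`, `hpt9`, `sdmt`).
#' @export
simulate_visit_trajectories <- function(baselines, events, followup, config,
                                        seed = 1L) {
  sp <- config$visit_schedule$spacing_days
  horizon <- config$visit_schedule$horizon_days
  if (any(events$time_days > horizon))
    stop("visit grid horizon is shorter than an event time")
  need <- c("t25fw_base", "hpt9_base", "sdmt_base")
  miss <- setdiff(need, names(baselines))
  if (length(miss)) stop("baselines lack tier-2 field(s): ",
                         paste(miss, collapse = ", "))
  set.seed(derive_seed(seed, 2L))
  last_day <- pmin(sp * floor(followup / sp), sp * floor(horizon / sp))
  ev <- split(events, events$patient_id)
  noise <- config$trajectory_noise
  rows <- lapply(baselines$patient_id, function(pid) {
    i <- match(pid, baselines$patient_id)
    days <- seq(0, last_day[[pid]], by = sp)
    e <- ev[[pid]]
    etime <- function(oc) {
      r <- e[e$outcome == oc, ]
      if (nrow(r) && r$event[1L] == 1L) r$time_days[1L] else Inf
    }
    nvis <- length(days)
    z <- matrix(stats::rnorm(nvis * 4L), nvis, 4L)
    z[1L, ] <- 0  # baseline visit is measured without noise
    base_edss <- baselines$edss[i]
    d_edss <- if (base_edss <= 5.0) 1.0 else 0.5
    edss <- ifelse(days >= etime("EDSS"),
                   pmin(10, base_edss + d_edss), base_edss) +
      noise[["edss"]] * z[, 1L]
    edss <- pmin(10, pmax(0, round(edss * 2) / 2))
    t25 <- ifelse(days >= etime("T25FW"),
                  baselines$t25fw_base[i] * 1.25,
                  baselines$t25fw_base[i]) + noise[["t25fw"]] * z[, 2L]
    t25 <- pmax(0.5, t25)
    hp9 <- ifelse(days >= etime("9HPT"),
                  baselines$hpt9_base[i] * 1.25,
                  baselines$hpt9_base[i]) + noise[["hpt9"]] * z[, 3L]
    hp9 <- pmax(0.5, hp9)
    sdmt <- ifelse(days >= etime("SDMT"),
                   pmax(0, baselines$sdmt_base[i] - 5),
                   baselines$sdmt_base[i]) + noise[["sdmt"]] * z[, 4L]
    sdmt <- pmin(110, pmax(0, round(sdmt)))
    data.frame(patient_id = pid, day = days, edss = edss, t25fw = t25,
               hpt9 = hp9, sdmt = sdmt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic trial
#'
#' Convenience wrapper: baselines, latent event times, and optionally the
#' visit-grid observation layer (grid-aligned events plus visit
#' trajectories).
#'
#' @param config a `synthetic_trial_config`.
#' @param seed master seed.
#' @param visits also generate visit trajectories and grid-aligned events
#'   (default `FALSE`; the returned event table is then the latent one).
#' @return list with `dataset` (a `trial_dataset`), `truth`, `followup`, and
#'   (when requested) `visits`.
#' @export
simulate_trial <- function(config, seed = 1L, visits = FALSE) {
  b <- simulate_baselines(config, seed)
  sim <- simulate_event_times(b, config, seed)
  if (visits) {
    snapped <- snap_events_to_grid(sim$events, sim$followup, config)
    vis <- simulate_visit_trajectories(b, snapped, sim$followup, config, seed)
    ds <- trial_dataset(b, snapped, provenance = "synthetic", seed = seed)
    list(dataset = ds, truth = sim$truth, followup = sim$followup,
         visits = vis)
  } else {
    ds <- trial_dataset(b, sim$events, provenance = "synthetic", seed = seed)
    list(dataset = ds, truth = sim$truth, followup = sim$followup)
  }
}
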