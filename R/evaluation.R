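#' Performance evaluation of a response score
#'
#' Discrimination is summarised by the AD(q) curve: the treatment hazard
#' ratio re-estimated inside the best-scoring fraction q of patients, traced
#' over q. A flat curve at the overall HR means no heterogeneity; the lower
#' the curve at small q, the more the benefit concentrates in the predicted
#' responders. Agreement is summarised by a calibration table of observed
#' subgroup log HRs against mean predicted scores across score quartiles.
#' Replicability is the fraction of bootstrap training/validation resamples
#' in which the re-selected score passes the validation rule.
#'
#' @name evaluation
NULL

#' Treatment effect by subgroup
#'
#' Unadjusted treatment-only Cox fit per subgroup with a 95% Wald CI on the
#' log scale. Subgroups with a single arm or no events are flagged not
#' evaluable.
#'
#' @param dataset a `trial_dataset`.
#' @param outcome outcome name.
#' @param labels named character vector of group labels keyed by patient id.
#' @return data frame with one row per group: `group`, `hr`, `ci_low`,
#'   `ci_high`, `n`, `events`, `evaluable`.
#' @export
subgroup_hr <- function(dataset, outcome, labels) {
  df <- outcome_frame(dataset, outcome)
  lab <- labels[match(df$patient_id, names(labels))]
  groups <- sort(unique(stats::na.omit(lab)))
  rows <- lapply(groups, function(g) {
    sel <- which(lab == g)
    est <- .cox_hr_ci(df$time[sel], df$event[sel], df$treat[sel])
    if (is.null(est))
      data.frame(group = g, hr = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, log_hr = NA_real_, n = length(sel),
                 events = sum(df$event[sel]), evaluable = FALSE)
    else
      data.frame(group = g, hr = est$hr, ci_low = est$ci_low,
                 ci_high = est$ci_high, log_hr = est$log_hr, n = est$n,
                 events = est$events, evaluable = TRUE)
  })
  do.call(rbind, rows)
}

#' Treatment-by-covariate interaction test
#'
#' Cox fit with treatment, the covariate (a continuous score or a binary
#' responder indicator) and their product; returns the Wald p-value of the
#' product term. Degenerate input (constant covariate, non-convergence)
#' returns `NA`.
#'
#' @param dataset a `trial_dataset`.
#' @param outcome outcome name.
#' @param covariate numeric vector (aligned with `ids`).
#' @param ids patient ids matching `covariate` (defaults to its names).
#' @return Wald p-value, or `NA` if not evaluable.
#' @export
interaction_test <- function(dataset, outcome, covariate,
                             ids = names(covariate)) {
  df <- outcome_frame(dataset, outcome)
  z <- covariate[match(df$patient_id, ids)]
  ok <- !is.na(z)
  df <- df[ok, , drop = FALSE]; z <- z[ok]
  if (length(unique(z)) < 2L || length(unique(df$treat)) < 2L ||
      sum(df$event) < 2L) return(NA_real_)
  fit <- tryCatch(
    suppressWarnings(survival::coxph(
      survival::Surv(df$time, df$event) ~ df$treat * z, ties = "efron")),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  cf <- coef(fit); se <- sqrt(diag(fit$var))
  i <- length(cf)
  if (!is.finite(cf[i]) || !is.finite(se[i]) || se[i] > 50) return(NA_real_)
  unname(2 * stats::pnorm(-abs(cf[i] / se[i])))
}

#' AD(q) discrimination curve
#'
#' For each q in the grid, the treatment HR is estimated among the fraction
#' q of patients with the lowest (most benefit-predicting) scores. The AUC
#' is the trapezoidal integral of the curve over the evaluable grid,
#' normalised by its q-span (a mean curve height on the HR scale). At q = 1
#' the subgroup is everyone, so the curve ends at the overall HR.
#'
#' @param dataset a `trial_dataset`.
#' @param outcome outcome name.
#' @param scores named score vector over the dataset's patients.
#' @param grid q grid in (0, 1], must include 1 (default 0.1 ... 1.0).
#' @return list of class `adq_curve` with `curve` (data frame q, hr,
#'   evaluable) and `auc`.
#' @export
adq_curve <- function(dataset, outcome, scores,
                      grid = seq(0.1, 1.0, by = 0.1)) {
  stopifnot(all(grid > 0), all(grid <= 1))
  if (!any(abs(grid - 1) < 1e-12)) stop("grid must include q = 1")
  grid <- sort(grid)
  df <- outcome_frame(dataset, outcome)
  sc <- scores[match(df$patient_id, names(scores))]
  rows <- lapply(grid, function(q) {
    thr <- stats::quantile(sc, q, type = 7)
    sel <- which(sc <= thr)
    est <- .cox_hr_ci(df$time[sel], df$event[sel], df$treat[sel])
    if (is.null(est))
      data.frame(q = q, hr = NA_real_, n = length(sel), evaluable = FALSE)
    else
      data.frame(q = q, hr = est$hr, n = est$n, evaluable = TRUE)
  })
  curve <- do.call(rbind, rows)
  ev <- curve[curve$evaluable, , drop = FALSE]
  auc <- if (nrow(ev) >= 2L) {
    span <- max(ev$q) - min(ev$q)
    sum(diff(ev$q) * (utils::head(ev$hr, -1) + utils::tail(ev$hr, -1)) / 2) /
      span
  } else if (nrow(ev) == 1L) ev$hr else NA_real_
  structure(list(curve = curve, auc = auc, outcome = outcome),
            class = "adq_curve")
}

#' Calibration table by score quantile bins
#'
#' Bins patients by score quantiles (default quartiles) and contrasts each
#' bin's mean predicted score with the observed treatment log HR and its
#' 95% CI. Bins that cannot be estimated are flagged and kept.
#'
#' @param dataset a `trial_dataset`.
#' @param outcome outcome name.
#' @param scores named score vector.
#' @param n_bins number of quantile bins (>= 2, default 4).
#' @return data frame with `bin`, `n`, `predicted_log_hr`, `observed_log_hr`,
#'   `ci_low`, `ci_high`, `evaluable` (CI columns on the log-HR scale).
#' @export
calibration <- function(dataset, outcome, scores, n_bins = 4L) {
  stopifnot(n_bins >= 2L)
  df <- outcome_frame(dataset, outcome)
  sc <- scores[match(df$patient_id, names(scores))]
  br <- unique(stats::quantile(sc, probs = seq(0, 1, length.out = n_bins + 1),
                               type = 7))
  bin <- if (length(br) < 2L) rep(1L, length(sc))  # constant score
  else cut(sc, breaks = br, include.lowest = TRUE, labels = FALSE)
  rows <- lapply(seq_len(n_bins), function(k) {
    sel <- which(bin == k)
    if (!length(sel))
      return(data.frame(bin = k, n = 0L, predicted_log_hr = NA_real_,
                        observed_log_hr = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, evaluable = FALSE))
    est <- .cox_hr_ci(df$time[sel], df$event[sel], df$treat[sel])
    data.frame(bin = k, n = length(sel), predicted_log_hr = mean(sc[sel]),
               observed_log_hr = if (is.null(est)) NA_real_ else est$log_hr,
               ci_low = if (is.null(est)) NA_real_ else log(est$ci_low),
               ci_high = if (is.null(est)) NA_real_ else log(est$ci_high),
               evaluable = !is.null(est))
  })
  do.call(rbind, rows)
}

#' Bootstrap replicability of the selection procedure
#'
#' Repeats the full selection pipeline on bootstrap resamples: resample the
#' dataset with replacement (or reuse it as-is with `resample = FALSE`),
#' split it into training/validation sets, rank all candidate subsets,
#' select the top one and apply the validation rule. The pass rate is the
#' fraction of successful replicates in which the selected score validates.
#'
#' @param dataset full `trial_dataset`.
#' @param outcome outcome name.
#' @param variables variable set to search.
#' @param n_replicates number of bootstrap replicates (default 500).
#' @param seed master seed.
#' @param fraction training fraction.
#' @param resample bootstrap-resample before each split (default `TRUE`).
#' @param method,hr_rule passed through to the selection machinery.
#' @return list of class `replicability_result` with `pass_rate`,
#'   `n_replicates`, `n_failed`, `subset_frequency` and the per-replicate
#'   `log` data frame.
#' @export
replicability <- function(dataset, outcome,
                          variables = variable_set("CLINICAL_PRACTICE"),
                          n_replicates = 500L, seed = 1L, fraction = 0.7,
                          resample = TRUE, method = "two_fit",
                          hr_rule = "ratio") {
  ids <- dataset$baselines$patient_id
  n <- length(ids)
  logs <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rs <- derive_seed(seed, 100L + r)
    res <- tryCatch({
      set.seed(rs)
      boot <- if (resample) {
        idx <- sample.int(n, n, replace = TRUE)
        b <- dataset$baselines[idx, , drop = FALSE]
        b$patient_id <- sprintf("B%05d", seq_len(n))  # de-duplicate ids
        e <- dataset$events[dataset$events$outcome == outcome, , drop = FALSE]
        e <- e[match(ids[idx], e$patient_id), , drop = FALSE]
        e$patient_id <- b$patient_id
        trial_dataset(b, e, provenance = "bootstrap")
      } else dataset
      sel <- select_response_score(boot, outcome, variables,
                                   fraction = fraction,
                                   seed = derive_seed(rs, 7L),
                                   method = method, hr_rule = hr_rule)
      data.frame(replicate = r, ok = TRUE,
                 subset = sel$ranking$table$subset[sel$selected_rank],
                 validated = isTRUE(sel$verdict$validated))
    }, error = function(e)
      data.frame(replicate = r, ok = FALSE, subset = NA_character_,
                 validated = NA))
    logs[[r]] <- res
  }
  log <- do.call(rbind, logs)
  ok <- log[log$ok, , drop = FALSE]
  structure(list(
    pass_rate = if (nrow(ok)) mean(ok$validated) else NA_real_,
    n_replicates = n_replicates, n_failed = sum(!log$ok),
    subset_frequency = if (nrow(ok)) table(ok$subset) else table(character()),
    log = log), class = "replicability_result")
}

#' Kaplan-Meier summary tables
#'
#' Product-limit survival estimates per group and arm, exported as step
#' tables for plotting.
#'
#' @param dataset a `trial_dataset`.
#' @param outcome outcome name.
#' @param labels named group labels keyed by patient id (default: one group).
#' @return data frame with `group`, `arm`, `time`, `n_risk`, `n_event`,
#'   `surv`, `lower`, `upper`.
#' @export
km_summary <- function(dataset, outcome, labels = NULL) {
  df <- outcome_frame(dataset, outcome)
  lab <- if (is.null(labels)) rep("all", nrow(df))
  else labels[match(df$patient_id, names(labels))]
  rows <- list()
  for (g in sort(unique(stats::na.omit(lab)))) {
    for (a in c(0L, 1L)) {
      sel <- which(lab == g & df$treat == a)
      if (!length(sel)) next
      fit <- survival::survfit(
        survival::Surv(df$time[sel], df$event[sel]) ~ 1)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, arm = if (a == 1L) "treatment" else "control",
        time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
        surv = fit$surv, lower = fit$lower, upper = fit$upper)
    }
  }
  do.call(rbind, rows)
}
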