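#' Response-score models
#'
#' A response score is a linear combination of transformed baseline
#' covariates on the log hazard-ratio scale: `score(x) = intercept +
#' sum(coef_j * t_j(x_j))`. It is interpreted as the patient-specific log HR
#' of treatment versus control, so more negative scores predict larger
#' treatment benefit. Scores are built by fitting separate proportional-
#' hazards prognostic models in each arm and differencing their coefficients;
#' the intercept is the treatment main effect from a pooled model with
#' treatment-by-covariate interactions (uncentered covariates, so the
#' intercept is the log HR at transformed covariate value 0, matching the
#' published functional form).
#'
#' @name response-score
NULL

new_response_score <- function(outcome, intercept, coefficients,
                               provenance = "fitted", fit = NULL,
                               overall_hr = NULL) {
  structure(list(outcome = outcome, intercept = intercept,
                 coefficients = coefficients, provenance = provenance,
                 fit = fit, overall_hr = overall_hr),
            class = "response_score")
}

#' @export
print.response_score <- function(x, ...) {
  terms <- if (length(x$coefficients))
    paste(sprintf("%+.4g*%s", x$coefficients, names(x$coefficients)),
          collapse = " ")
  else ""
  cat("<response_score ", x$outcome, " [", x$provenance, "]> ",
      sprintf("%.4g ", x$intercept), terms, "\n", sep = "")
  invisible(x)
}

#' Load a published response-score model
#'
#' Returns one of the four published clinical-practice scores packaged with
#' the library, including its responder cut-off (the whole-group hazard
#' ratio for that outcome).
#'
#' @param outcome `"EDSS"`, `"9HPT"`, `"T25FW"`, or `"SDMT"`.
#' @return a `response_score` with provenance `"published"`.
#' @export
published_score <- function(outcome = c("EDSS", "9HPT", "T25FW", "SDMT")) {
  outcome <- match.arg(outcome)
  path <- system.file("extdata", "published_scores.json", package = "rshte",
                      mustWork = TRUE)
  fx <- jsonlite::fromJSON(path)$scores[[outcome]]
  new_response_score(outcome, fx$intercept, unlist(fx$coefficients),
                     provenance = "published", overall_hr = fx$overall_hr)
}

#' Fit a single-arm prognostic proportional-hazards model
#'
#' Partial-likelihood Cox regression (Efron ties) of one outcome's (time,
#' event) on the transformed covariates within one arm.
#'
#' @param dataset a `trial_dataset` with events.
#' @param arm `"treatment"` or `"control"`.
#' @param outcome outcome name.
#' @param terms covariate term names (see [variable_set()]).
#' @return list with `arm`, `coefficients`, `var`, `loglik`, `n`, `events`,
#'   `converged`.
#' @export
fit_arm_model <- function(dataset, arm = c("treatment", "control"), outcome,
                          terms) {
  arm <- match.arg(arm)
  df <- outcome_frame(dataset, outcome)
  keep <- df$treat == as.integer(arm == "treatment")
  df <- df[keep, , drop = FALSE]
  if (sum(df$event) < 1L) stop("no events in the ", arm, " arm for ", outcome)
  b <- dataset$baselines[match(df$patient_id, dataset$baselines$patient_id), ,
                         drop = FALSE]
  X <- covariate_matrix(b, terms)
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(df$time, df$event) ~ X, ties = "efron",
                    control = survival::coxph.control(eps = 1e-09,
                                                      iter.max = 100)),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  beta <- stats::setNames(unname(coef(fit)), terms)
  if (any(!is.finite(beta)) || any(abs(beta) > 50)) converged <- FALSE
  list(arm = arm, coefficients = beta, var = fit$var,
       loglik = fit$loglik[2L], n = nrow(df), events = sum(df$event),
       converged = converged)
}

# pooled model with treatment main effect and treatment x covariate
# interactions; uncentered covariates
.pooled_interaction_fit <- function(dataset, outcome, terms) {
  df <- outcome_frame(dataset, outcome)
  b <- dataset$baselines[match(df$patient_id, dataset$baselines$patient_id), ,
                         drop = FALSE]
  converged <- TRUE
  hd <- function(w) { converged <<- FALSE; invokeRestart("muffleWarning") }
  if (length(terms)) {
    X <- covariate_matrix(b, terms)
    XI <- X * df$treat
    colnames(XI) <- paste0("treat_x_", terms)
    fit <- withCallingHandlers(
      survival::coxph(survival::Surv(df$time, df$event) ~ df$treat + X + XI,
                      ties = "efron",
                      control = survival::coxph.control(eps = 1e-09,
                                                        iter.max = 100)),
      warning = hd)
    cf <- coef(fit)
    list(intercept = unname(cf[1L]),
         interaction = stats::setNames(
           unname(cf[(1L + length(terms) + 1L):(1L + 2L * length(terms))]),
           terms),
         var = fit$var, converged = converged)
  } else {
    fit <- withCallingHandlers(
      survival::coxph(survival::Surv(df$time, df$event) ~ df$treat,
                      ties = "efron"),
      warning = hd)
    list(intercept = unname(coef(fit)[1L]), interaction = numeric(0),
         var = fit$var, converged = converged)
  }
}

#' Build a response score from a training dataset
#'
#' Default method (`"two_fit"`, the literal construction): fit one
#' prognostic Cox model per arm and take the treatment-minus-control
#' coefficient difference as the score slopes. The alternative (`"pooled"`)
#' takes the slopes from the treatment-by-covariate interaction terms of a
#' single pooled model; the two agree asymptotically. In both methods the
#' intercept is the treatment main effect of the pooled interaction model
#' with uncentered covariates (the log HR at transformed covariate 0). With
#' an empty subset the score reduces to the overall treatment log HR.
#'
#' @param train training `trial_dataset`.
#' @param outcome outcome name.
#' @param terms covariate term names (may be empty).
#' @param method `"two_fit"` (default) or `"pooled"`.
#' @return a `response_score` (provenance `"fitted"`); non-convergence is
#'   flagged in `$fit$converged`.
#' @export
build_response_score <- function(train, outcome, terms,
                                 method = c("two_fit", "pooled")) {
  method <- match.arg(method)
  pooled <- .pooled_interaction_fit(train, outcome, terms)
  if (length(terms) == 0L) {
    return(new_response_score(outcome, pooled$intercept, numeric(0),
                              fit = list(method = method,
                                         converged = pooled$converged)))
  }
  if (method == "two_fit") {
    ft <- fit_arm_model(train, "treatment", outcome, terms)
    fc <- fit_arm_model(train, "control", outcome, terms)
    slopes <- ft$coefficients - fc$coefficients
    conv <- ft$converged && fc$converged && pooled$converged
    fit <- list(method = method, converged = conv,
                treatment = ft, control = fc)
  } else {
    slopes <- pooled$interaction
    conv <- pooled$converged
    fit <- list(method = method, converged = conv)
  }
  new_response_score(outcome, pooled$intercept, slopes, fit = fit)
}

#' Score patients with a response-score model
#'
#' @param model a `response_score`.
#' @param baselines baseline table with every variable the model needs
#'   (an informative error names any missing one).
#' @return named numeric vector of scores (log HR scale); `exp(score)` is
#'   the predicted individual hazard ratio.
#' @export
score_patients <- function(model, baselines) {
  s <- rep(model$intercept, nrow(baselines))
  if (length(model$coefficients)) {
    X <- covariate_matrix(baselines, names(model$coefficients))
    s <- s + drop(X %*% model$coefficients)
  }
  stats::setNames(s, baselines$patient_id)
}

#' Classify patients into responders and non-responders
#'
#' Two threshold conventions are supported: `"train_quartile"` uses the
#' first quartile (type-7 quantile) of a reference training-score
#' distribution, labelling the best-scoring 25% responders;
#' `"overall_hr"` uses the log of the whole-group hazard ratio. In both,
#' a patient is a responder when their score is less than or equal to the
#' threshold (inclusive at ties).
#'
#' @param scores named numeric score vector.
#' @param threshold_kind `"train_quartile"` or `"overall_hr"`.
#' @param reference training scores (for `"train_quartile"`) or the overall
#'   hazard ratio (for `"overall_hr"`, must be positive).
#' @return data frame with `patient_id`, `score`, `hr`, `threshold`,
#'   `threshold_kind`, `label`.
#' @export
classify <- function(scores, threshold_kind = c("train_quartile",
                                                "overall_hr"),
                     reference) {
  threshold_kind <- match.arg(threshold_kind)
  threshold <- switch(threshold_kind,
    train_quartile = unname(stats::quantile(reference, 0.25, type = 7)),
    overall_hr = {
      if (!is.numeric(reference) || length(reference) != 1L || reference <= 0)
        stop("overall HR must be a single positive number")
      log(reference)
    })
  data.frame(patient_id = names(scores) %||% seq_along(scores),
             score = unname(scores), hr = exp(unname(scores)),
             threshold = threshold, threshold_kind = threshold_kind,
             label = ifelse(scores <= threshold, "responder",
                            "non_responder"),
             stringsAsFactors = FALSE)
}
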