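#' All-subset response-score selection
#'
#' The candidate scores are built from every non-empty subset of the chosen
#' baseline variable set (2^n - 1 models). On the training set each
#' candidate classifies patients at the first quartile of its own score
#' distribution, the treatment effect (unadjusted hazard ratio) is estimated
#' separately in responders and non-responders, and candidates are ranked
#' ascending by the responder/non-responder HR ratio: the smallest ratio
#' marks the strongest separation. The top-ranked convergent candidate is
#' then tested on held-out validation data, where it is "validated" when the
#' HR ratio is below 0.80 and/or the treatment-by-responder interaction p is
#' below 0.20 (a deliberately liberal threshold, interaction tests being
#' low-powered).
#'
#' @name model-selection
NULL

#' Enumerate non-empty covariate subsets
#'
#' @param variables character vector of term names (at most 20).
#' @return list of all 2^n - 1 non-empty subsets, ordered by size then
#'   lexicographically.
#' @export
enumerate_subsets <- function(variables) {
  n <- length(variables)
  if (n < 1L) stop("need at least one variable")
  if (n > 20L) stop("more than 20 variables (", n,
                    "): prune the candidate set before subset search")
  subs <- unlist(lapply(seq_len(n), function(k) {
    m <- utils::combn(sort(variables), k, simplify = FALSE)
    m[order(vapply(m, paste, "", collapse = "\r"))]
  }), recursive = FALSE)
  # restore the caller's variable order inside each subset
  lapply(subs, function(s) variables[sort(match(s, variables))])
}

# treatment HR inside each classification stratum; NULL entries not evaluable
.stratum_hrs <- function(dataset, outcome, labels) {
  df <- outcome_frame(dataset, outcome)
  lab <- labels[match(df$patient_id, names(labels))]
  resp <- .cox_hr_ci(df$time[lab == "responder"],
                     df$event[lab == "responder"],
                     df$treat[lab == "responder"])
  nonr <- .cox_hr_ci(df$time[lab == "non_responder"],
                     df$event[lab == "non_responder"],
                     df$treat[lab == "non_responder"])
  list(responders = resp, non_responders = nonr)
}

#' Rank candidate subsets on the training set
#'
#' @param train training `trial_dataset`.
#' @param outcome outcome name.
#' @param variables variable set to search over (term names).
#' @param method passed to [build_response_score()].
#' @return list of class `candidate_ranking`: `table` (one row per subset
#'   with training HRs, the HR ratio and validity), and `models` (the fitted
#'   `response_score` objects, in ranked order).
#' @export
rank_candidates <- function(train, outcome, variables,
                            method = "two_fit") {
  subsets <- enumerate_subsets(variables)
  cand <- lapply(subsets, function(ss) {
    rs <- tryCatch(build_response_score(train, outcome, ss, method = method),
                   error = function(e) NULL)
    valid <- !is.null(rs) && isTRUE(rs$fit$converged)
    hr_r <- hr_n <- ratio <- NA_real_
    if (!is.null(rs)) {
      sc <- score_patients(rs, train$baselines)
      cl <- classify(sc, "train_quartile", reference = sc)
      hrs <- .stratum_hrs(train, outcome,
                          stats::setNames(cl$label, cl$patient_id))
      if (!is.null(hrs$responders)) hr_r <- hrs$responders$hr
      if (!is.null(hrs$non_responders)) hr_n <- hrs$non_responders$hr
      ratio <- hr_r / hr_n
      if (!is.finite(ratio)) { ratio <- NA_real_; valid <- FALSE }
    } else valid <- FALSE
    list(subset = ss, rs = rs, hr_resp = hr_r, hr_nonresp = hr_n,
         ratio = ratio, valid = valid)
  })
  if (!any(vapply(cand, `[[`, TRUE, "valid")))
    stop("no candidate subset converged")
  key_ratio <- vapply(cand, function(c)
    if (c$valid) c$ratio else Inf, numeric(1))
  key_size <- vapply(cand, function(c) length(c$subset), integer(1))
  key_lex <- vapply(cand, function(c) paste(c$subset, collapse = "+"),
                    character(1))
  ord <- order(key_ratio, key_size, key_lex)
  cand <- cand[ord]
  tab <- data.frame(
    rank = seq_along(cand),
    subset = vapply(cand, function(c) paste(c$subset, collapse = "+"), ""),
    n_vars = vapply(cand, function(c) length(c$subset), integer(1)),
    train_hr_responders = vapply(cand, `[[`, 1, "hr_resp"),
    train_hr_nonresponders = vapply(cand, `[[`, 1, "hr_nonresp"),
    hr_ratio = vapply(cand, `[[`, 1, "ratio"),
    valid = vapply(cand, `[[`, TRUE, "valid"),
    stringsAsFactors = FALSE)
  structure(list(table = tab, models = lapply(cand, `[[`, "rs"),
                 outcome = outcome, variables = variables, method = method),
            class = "candidate_ranking")
}

#' Apply the validation rule to a selected score
#'
#' Classifies validation patients at the log overall-HR cut-off, estimates
#' the treatment HR in responders and non-responders, and evaluates the two
#' validation criteria: the HR criterion (responder/non-responder HR ratio,
#' or with `hr_rule = "responders"` the responders' HR itself, below 0.80)
#' and the interaction criterion (treatment-by-responder Wald p below 0.20).
#' A stratum without events makes its criterion not evaluable; the verdict
#' then rests on the other.
#'
#' @param model the selected `response_score`.
#' @param validation_data validation `trial_dataset` (disjoint from
#'   training).
#' @param overall_hr whole-group hazard ratio used as the classification
#'   cut-off.
#' @param hr_rule `"ratio"` (default) or `"responders"`.
#' @param hr_cutoff HR criterion cut-off (default 0.80).
#' @param p_cutoff interaction criterion cut-off (default 0.20).
#' @return list of class `validation_verdict` with stratum HRs (with CIs),
#'   binary and continuous interaction p-values, the two criterion flags and
#'   `validated` (their OR).
#' @export
apply_validation_rule <- function(model, validation_data, overall_hr,
                                  hr_rule = c("ratio", "responders"),
                                  hr_cutoff = 0.80, p_cutoff = 0.20) {
  hr_rule <- match.arg(hr_rule)
  sc <- score_patients(model, validation_data$baselines)
  cl <- classify(sc, "overall_hr", reference = overall_hr)
  labels <- stats::setNames(cl$label, cl$patient_id)
  hrs <- .stratum_hrs(validation_data, model$outcome, labels)
  ratio <- if (!is.null(hrs$responders) && !is.null(hrs$non_responders))
    hrs$responders$hr / hrs$non_responders$hr else NA_real_
  hr_stat <- switch(hr_rule,
                    ratio = ratio,
                    responders = if (!is.null(hrs$responders))
                      hrs$responders$hr else NA_real_)
  hr_criterion <- if (is.na(hr_stat)) NA else hr_stat < hr_cutoff
  p_binary <- interaction_test(validation_data, model$outcome,
                               as.numeric(labels == "responder"),
                               ids = names(labels))
  p_cont <- interaction_test(validation_data, model$outcome, sc,
                             ids = names(sc))
  interaction_criterion <- if (is.na(p_binary)) NA else p_binary < p_cutoff
  validated <- isTRUE(hr_criterion) || isTRUE(interaction_criterion)
  structure(list(outcome = model$outcome, overall_hr = overall_hr,
                 threshold = log(overall_hr),
                 hr_responders = hrs$responders,
                 hr_nonresponders = hrs$non_responders,
                 hr_ratio = ratio, hr_statistic = hr_stat,
                 hr_criterion_met = hr_criterion,
                 p_interaction_binary = p_binary,
                 p_interaction_continuous = p_cont,
                 interaction_criterion_met = interaction_criterion,
                 validated = validated,
                 n_responders = sum(labels == "responder"),
                 n_nonresponders = sum(labels == "non_responder")),
            class = "validation_verdict")
}

#' Select and validate a response score for one outcome
#'
#' Runs the full selection sequence: split the dataset, rank all candidate
#' subsets on the training set, pick the top-ranked convergent candidate,
#' estimate the whole-group HR on the full dataset, and apply the validation
#' rule on the validation set.
#'
#' @param dataset full `trial_dataset`.
#' @param outcome outcome name.
#' @param variables variable set to search (default clinical practice set).
#' @param fraction training fraction (default 0.7).
#' @param seed split seed.
#' @param method passed to [build_response_score()].
#' @param hr_rule,hr_cutoff,p_cutoff passed to [apply_validation_rule()].
#' @return list of class `selection_result` with the split, ranking, selected
#'   model, overall HR and verdict.
#' @export
select_response_score <- function(dataset, outcome,
                                  variables = variable_set("CLINICAL_PRACTICE"),
                                  fraction = 0.7, seed = 1L,
                                  method = "two_fit",
                                  hr_rule = "ratio", hr_cutoff = 0.80,
                                  p_cutoff = 0.20) {
  sp <- split_train_validation(dataset, fraction, seed)
  ranking <- rank_candidates(sp$train, outcome, variables, method = method)
  sel_idx <- which(ranking$table$valid)[1L]
  selected <- ranking$models[[sel_idx]]
  df <- outcome_frame(dataset, outcome)
  overall <- .cox_hr_ci(df$time, df$event, df$treat)
  if (is.null(overall)) stop("overall treatment effect not estimable")
  verdict <- apply_validation_rule(selected, sp$validation, overall$hr,
                                   hr_rule = hr_rule, hr_cutoff = hr_cutoff,
                                   p_cutoff = p_cutoff)
  structure(list(outcome = outcome, split = sp, ranking = ranking,
                 selected = selected, selected_rank = sel_idx,
                 overall = overall, verdict = verdict,
                 settings = list(variables = variables, fraction = fraction,
                                 seed = seed, method = method,
                                 hr_rule = hr_rule, hr_cutoff = hr_cutoff,
                                 p_cutoff = p_cutoff)),
            class = "selection_result")
}
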