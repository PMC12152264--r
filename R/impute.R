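#' Multiple imputation by chained equations
#'
#' Fills missing baseline covariates with an iterative conditional-regression
#' scheme and returns `m` completed copies of the dataset. Each variable with
#' missing values is regressed on all other baseline covariates: continuous
#' variables use a Bayesian linear regression with posterior-predictive normal
#' draws, binary variables a logistic regression with coefficient draws,
#' counts are drawn from the linear model then rounded and clipped at zero,
#' and bounded ordinal scores (EDSS) rounded to the 0.5 grid and clipped to
#' [0, 10]. The chain cycles `maxit` times per imputation. Observed cells are
#' never altered; arm and outcomes must be complete.
#'
#' @param dataset a `trial_dataset`; missingness allowed only in baseline
#'   covariates.
#' @param m number of completed datasets (default 10).
#' @param seed integer seed.
#' @param maxit chained-equation cycles per imputation (default 10).
#' @return list of `m` completed `trial_dataset` objects.
#' @export
mice_impute <- function(dataset, m = 10L, seed = 1L, maxit = 10L) {
  b <- dataset$baselines
  if (anyNA(b$arm)) stop("missingness in 'arm' is not supported")
  covars <- intersect(c("age", "sex", "edss", "relapses_2y",
                        "disease_duration", "t25fw_base", "hpt9_base",
                        "sdmt_base", "gd_count", "t2_volume", "cgm_volume",
                        "thalamus_volume", "gfap", "nfl"), names(b))
  all_missing <- covars[vapply(covars, function(v) all(is.na(b[[v]])),
                               logical(1))]
  if (length(all_missing))
    stop("variable(s) 100% missing: ", paste(all_missing, collapse = ", "))
  has_na <- covars[vapply(covars, function(v) anyNA(b[[v]]), logical(1))]
  if (!length(has_na)) {
    return(replicate(m, dataset, simplify = FALSE))
  }

  # numeric working copy: sex coded as male indicator
  work0 <- b[covars]
  if ("sex" %in% covars)
    work0$sex <- as.numeric(tolower(as.character(b$sex)) == "male")
  work0[] <- lapply(work0, as.numeric)
  na_idx <- lapply(work0, function(x) which(is.na(x)))

  type_of <- function(v) {
    if (v == "sex") "binary"
    else if (v %in% c("relapses_2y", "gd_count")) "count"
    else if (v == "edss") "edss"
    else "continuous"
  }

  set.seed(as.integer(seed))
  out <- vector("list", m)
  for (k in seq_len(m)) {
    work <- work0
    # initialize missing cells by resampling observed values
    for (v in has_na) {
      obs <- work[[v]][!is.na(work[[v]])]
      work[[v]][na_idx[[v]]] <- sample(obs, length(na_idx[[v]]),
                                       replace = TRUE)
    }
    for (it in seq_len(maxit)) {
      for (v in has_na) {
        idx <- na_idx[[v]]
        preds <- setdiff(covars, v)
        X <- cbind(1, as.matrix(work[preds]))
        obs <- setdiff(seq_len(nrow(X)), idx)
        y <- work0[[v]]
        draw <- .impute_draw(y[obs], X[obs, , drop = FALSE],
                             X[idx, , drop = FALSE], type_of(v))
        work[[v]][idx] <- draw
      }
    }
    comp <- b
    for (v in has_na) {
      val <- work[[v]]
      if (v == "sex") comp$sex <- ifelse(val == 1, "male", "female")
      else comp[[v]] <- val
    }
    out[[k]] <- trial_dataset(comp, dataset$events,
                              provenance = paste0(dataset$provenance,
                                                  " (imputation ", k, ")"),
                              seed = dataset$seed)
  }
  out
}

# one posterior-predictive draw for the missing cells of a variable
.impute_draw <- function(y_obs, X_obs, X_mis, type) {
  if (nrow(X_mis) == 0L) return(numeric(0))
  if (type == "binary") {
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X_obs, y_obs,
                                      family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit$coefficients))) {
      p <- rep(mean(y_obs), nrow(X_mis))
    } else {
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      p <- stats::plogis(drop(X_mis %*% beta))
    }
    return(stats::rbinom(nrow(X_mis), 1L, p))
  }
  # Bayesian linear regression via QR; fall back to marginal resampling
  qr_ <- qr(X_obs)
  rank <- qr_$rank
  n <- length(y_obs)
  beta_hat <- qr.coef(qr_, y_obs)
  beta_hat[is.na(beta_hat)] <- 0
  res <- y_obs - drop(X_obs %*% beta_hat)
  df <- max(n - rank, 2L)
  sigma2 <- sum(res^2) / stats::rchisq(1L, df)
  R <- qr.R(qr_)[seq_len(rank), seq_len(rank), drop = FALSE]
  keep <- qr_$pivot[seq_len(rank)]
  beta_draw <- beta_hat
  pert <- tryCatch(backsolve(R, stats::rnorm(rank)) * sqrt(sigma2),
                   error = function(e) rep(0, rank))
  beta_draw[keep] <- beta_draw[keep] + pert
  mu <- drop(X_mis %*% beta_draw)
  draw <- mu + stats::rnorm(nrow(X_mis)) * sqrt(sigma2)
  switch(type,
         count = pmax(0, round(draw)),
         edss = pmin(10, pmax(0, round(draw * 2) / 2)),
         continuous = draw)
}

#' Rubin pooling of repeated estimates
#'
#' Combines per-imputation point estimates and variances: pooled estimate is
#' the mean; total variance is the within-imputation mean plus (1 + 1/m)
#' times the between-imputation variance.
#'
#' @param estimates numeric vector (or matrix, one row per imputation).
#' @param variances matching variances.
#' @return list with `estimate`, `variance`, `se`.
#' @export
pool_rubin <- function(estimates, variances) {
  est <- as.matrix(estimates); v <- as.matrix(variances)
  m <- nrow(est)
  qbar <- colMeans(est)
  ubar <- colMeans(v)
  bvar <- if (m > 1) apply(est, 2, stats::var) else 0 * qbar
  total <- ubar + (1 + 1 / m) * bvar
  list(estimate = qbar, variance = total, se = sqrt(total))
}
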