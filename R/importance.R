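#' Conditional permutation variable importance
#'
#' Ranks the baseline variables that drive the responder/non-responder
#' classification. A random-forest classifier of the responder label on the
#' candidate variables is fitted, then each variable's importance is the
#' mean increase in per-tree out-of-bag misclassification after permuting
#' that variable *within strata* built from its correlated co-variables
#' (quartile bins of every covariate with absolute correlation above
#' `cor_threshold`). Conditioning on correlated covariates prevents a
#' variable from borrowing importance from its correlates. Importances are
#' reported raw (`vi`) and normalised to the maximum (`pct_vi`, top variable
#' = 100; negative noise clipped to 0 in `pct_vi`, raw value retained).
#'
#' @param baselines baseline table.
#' @param labels named responder labels (`"responder"`/`"non_responder"`)
#'   keyed by patient id; both classes must be present.
#' @param variables covariate term names to rank.
#' @param num_trees forest size (default 1000).
#' @param cor_threshold correlation threshold defining the conditioning set
#'   (default 0.2).
#' @param n_perm permutations averaged per variable (default 5).
#' @param seed integer seed.
#' @return data frame with `variable`, `vi`, `pct_vi`, sorted by importance.
#' @export
variable_importance <- function(baselines, labels,
                                variables = variable_set("CLINICAL_PRACTICE"),
                                num_trees = 1000L, cor_threshold = 0.2,
                                n_perm = 5L, seed = 1L) {
  y <- factor(labels[match(baselines$patient_id, names(labels))])
  if (nlevels(droplevels(y)) < 2L)
    stop("responder labels contain a single class")
  X <- as.data.frame(covariate_matrix(baselines, variables))
  dat <- cbind(X, .label = y)
  set.seed(as.integer(seed))
  rf <- ranger::ranger(dependent.variable.name = ".label", data = dat,
                       num.trees = num_trees, keep.inbag = TRUE,
                       num.threads = 1L, seed = as.integer(seed))
  inbag <- matrix(unlist(rf$inbag.counts), nrow = nrow(dat))
  oob <- inbag == 0L
  per_tree_err <- function(newdata) {
    pred <- stats::predict(rf, data = newdata, predict.all = TRUE,
                           num.threads = 1L)$predictions
    wrong <- pred != as.integer(y)
    colSums(wrong & oob) / pmax(colSums(oob), 1L)
  }
  base_err <- per_tree_err(dat)
  cm <- suppressWarnings(stats::cor(X))
  cm[!is.finite(cm)] <- 0
  vi <- vapply(variables, function(v) {
    cond <- setdiff(variables[abs(cm[v, ]) > cor_threshold], v)
    strata <- if (length(cond)) {
      key <- apply(vapply(cond, function(u) {
        br <- unique(stats::quantile(X[[u]], probs = seq(0, 1, 0.25),
                                     type = 7))
        if (length(br) < 2L) rep(1L, nrow(X))
        else as.integer(cut(X[[u]], br, include.lowest = TRUE))
      }, integer(nrow(X))), 1L, paste, collapse = "|")
      key
    } else rep("all", nrow(X))
    mean(vapply(seq_len(n_perm), function(p) {
      perm <- dat
      for (s in unique(strata)) {
        idx <- which(strata == s)
        if (length(idx) > 1L) perm[[v]][idx] <- sample(perm[[v]][idx])
      }
      mean(per_tree_err(perm) - base_err)
    }, numeric(1)))
  }, numeric(1))
  vmax <- max(vi)
  pct <- if (vmax > 0) 100 * pmax(vi, 0) / vmax else rep(NA_real_, length(vi))
  out <- data.frame(variable = variables, vi = unname(vi),
                    pct_vi = unname(pct), stringsAsFactors = FALSE)
  out[order(-out$vi), , drop = FALSE]
}
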