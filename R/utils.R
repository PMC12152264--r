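#' Round half up
#'
#' Rounds to `digits` decimals with ties broken upward (toward +Inf), the
#' convention used for all printed score and hazard-ratio displays.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(-0.115, 0.625), 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# derive a child seed from a master seed; kept below 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Wald HR with 95% CI from a treatment-only Cox fit; NULL if not evaluable
.cox_hr_ci <- function(time, event, treat, conf = 0.95) {
  ok <- is.finite(time) & !is.na(event) & !is.na(treat)
  time <- time[ok]; event <- event[ok]; treat <- treat[ok]
  if (length(unique(treat)) < 2L || sum(event) < 1L) return(NULL)
  fit <- tryCatch(
    suppressWarnings(survival::coxph(survival::Surv(time, event) ~ treat,
                                     ties = "efron")),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  b <- unname(coef(fit)[1L]); se <- sqrt(diag(fit$var))[1L]
  if (!is.finite(b) || !is.finite(se) || se > 50) return(NULL)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(log_hr = b, se = se, hr = exp(b),
       ci_low = exp(b - z * se), ci_high = exp(b + z * se),
       n = length(time), events = sum(event),
       n_treat = sum(treat == 1), n_control = sum(treat == 0))
}
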