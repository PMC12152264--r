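#' Confirmed-progression outcomes from visit-level scores
#'
#' The four time-to-progression endpoints are derived from longitudinal
#' visit scores. Progression must be *confirmed*: the worsening observed at a
#' visit must still hold at the next scheduled visit at least a minimum
#' window later (3 months for EDSS/T25FW/9HPT, 6 months for SDMT). The event
#' time is always the day of the initial qualifying worsening; unconfirmed
#' worsening, including worsening at the final visit, is censored at the last
#' visit with a usable score.
#'
#' @name progression-outcomes
NULL

# generic confirmed-progression scan.
# days/values: one patient's visits (day 0 = baseline), qualifying when
# `worse(value)` is TRUE; confirmation at the first later visit >= window
# days after the qualifying one, with (if sustained) all intermediate visits
# also qualifying.
.confirmed_event <- function(days, values, worse, window, sustained) {
  keep <- !is.na(values)
  days <- days[keep]; values <- values[keep]
  if (!length(days)) stop("no usable visits")
  last_day <- days[length(days)]
  qual <- which(worse(values))
  qual <- qual[qual > 1L]  # baseline visit cannot be the event
  for (i in qual) {
    j <- which(days >= days[i] + window)
    if (!length(j)) next
    j <- j[1L]
    ok <- worse(values[j])
    if (ok && sustained && j > i + 1L)
      ok <- all(worse(values[(i + 1L):(j - 1L)]))
    if (ok) return(list(time_days = days[i], event = TRUE))
  }
  list(time_days = last_day, event = FALSE)
}

.baseline_value <- function(visits, field) {
  i <- which(visits$day == 0)
  if (!length(i) || is.na(visits[[field]][i[1L]]))
    stop("no baseline (day 0) value for '", field, "'")
  visits[[field]][i[1L]]
}

.order_visits <- function(visits) {
  stopifnot(all(visits$day >= 0))
  visits <- visits[order(visits$day), , drop = FALSE]
  if (anyDuplicated(visits$day)) stop("duplicate visit days for a patient")
  visits
}

#' EDSS confirmed progression for one patient
#'
#' Worsening threshold is a 1.0-point increase when baseline EDSS is at most
#' 5.0 and a 0.5-point increase when baseline is 5.5 or above, confirmed at
#' the next scheduled visit at least `confirm_window_days` later.
#'
#' @param visits data frame with columns `day` and `edss` for one patient
#'   (day 0 = baseline).
#' @param confirm_window_days minimum confirmation gap (default 84, i.e.
#'   3 months).
#' @param sustained require the threshold to hold at all intermediate visits
#'   (default `TRUE`).
#' @return list with `time_days` and `event`.
#' @export
edss_progression <- function(visits, confirm_window_days = 84,
                             sustained = TRUE) {
  visits <- .order_visits(visits)
  base <- .baseline_value(visits, "edss")
  delta <- if (base <= 5.0) 1.0 else 0.5
  .confirmed_event(visits$day, visits$edss,
                   function(v) v >= base + delta,
                   confirm_window_days, sustained)
}

#' Percent-worsening confirmed progression (T25FW / 9HPT)
#'
#' Event when the timed score worsens (increases) by at least `pct` from
#' baseline, confirmed as for EDSS.
#'
#' @param visits data frame with columns `day` and the score field.
#' @param score_field `"t25fw"` or `"hpt9"`.
#' @param pct worsening fraction (default 0.20).
#' @param confirm_window_days minimum confirmation gap (default 84).
#' @param sustained see [edss_progression()].
#' @return list with `time_days` and `event`.
#' @export
percent_worsening_progression <- function(visits, score_field = "t25fw",
                                          pct = 0.20,
                                          confirm_window_days = 84,
                                          sustained = TRUE) {
  visits <- .order_visits(visits)
  base <- .baseline_value(visits, score_field)
  if (base <= 0) stop("baseline ", score_field, " must be positive")
  thr <- base * (1 + pct)
  .confirmed_event(visits$day, visits[[score_field]],
                   function(v) v >= thr,
                   confirm_window_days, sustained)
}

#' SDMT confirmed progression
#'
#' Event when the SDMT score drops by at least 4 points from baseline,
#' confirmed at the next scheduled visit at least `confirm_window_days`
#' (default 168, i.e. 6 months) later.
#'
#' @param visits data frame with columns `day` and `sdmt`.
#' @param confirm_window_days minimum confirmation gap (default 168).
#' @param sustained see [edss_progression()].
#' @return list with `time_days` and `event`.
#' @export
sdmt_progression <- function(visits, confirm_window_days = 168,
                             sustained = TRUE) {
  visits <- .order_visits(visits)
  base <- .baseline_value(visits, "sdmt")
  .confirmed_event(visits$day, visits$sdmt,
                   function(v) v <= base - 4,
                   confirm_window_days, sustained)
}

.OUTCOME_FIELD <- c(EDSS = "edss", T25FW = "t25fw", `9HPT` = "hpt9",
                    SDMT = "sdmt")

#' Derive all confirmed-progression events from a visits table
#'
#' Applies the outcome-specific progression rules patient by patient and
#' returns a long event table.
#'
#' @param visits data frame with columns `patient_id`, `day`, and any of
#'   `edss`, `t25fw`, `hpt9`, `sdmt` (missing scores skip the visit for that
#'   outcome).
#' @param outcomes outcomes to derive (default all four).
#' @param confirm_window_days 3-month window in days (default 84).
#' @param sdmt_confirm_window_days 6-month window in days (default 168).
#' @param sustained see [edss_progression()].
#' @return data frame with `patient_id`, `outcome`, `time_days`, `event`.
#' @export
derive_progression <- function(visits,
                               outcomes = c("EDSS", "T25FW", "9HPT", "SDMT"),
                               confirm_window_days = 84,
                               sdmt_confirm_window_days = 168,
                               sustained = TRUE) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  split_v <- split(visits, visits$patient_id)
  rows <- lapply(names(split_v), function(pid) {
    v <- split_v[[pid]]
    do.call(rbind, lapply(outcomes, function(oc) {
      r <- switch(oc,
                  EDSS = edss_progression(v, confirm_window_days, sustained),
                  T25FW = percent_worsening_progression(
                    v, "t25fw", 0.20, confirm_window_days, sustained),
                  `9HPT` = percent_worsening_progression(
                    v, "hpt9", 0.20, confirm_window_days, sustained),
                  SDMT = sdmt_progression(v, sdmt_confirm_window_days,
                                          sustained))
      data.frame(patient_id = pid, outcome = oc,
                 time_days = r$time_days, event = as.integer(r$event),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
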