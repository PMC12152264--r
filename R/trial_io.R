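#' Trial dataset container
#'
#' Bundles a baseline table (one row per patient) with a long event table
#' (one row per patient x outcome). Patients in the event table must exist in
#' the baseline table, and each (patient, outcome) pair appears at most once.
#'
#' @param baselines data frame with at least `patient_id`, `arm` and the
#'   clinical covariates; `arm` is `"treatment"` or `"control"`.
#' @param events data frame with columns `patient_id`, `outcome`
#'   (`EDSS`, `T25FW`, `9HPT`, `SDMT`), `time_days`, `event` (0/1), or `NULL`.
#' @param provenance free-text label recorded with the dataset.
#' @param seed seed metadata for synthetic data (optional).
#' @return object of class `trial_dataset`.
#' @export
trial_dataset <- function(baselines, events = NULL, provenance = "unspecified",
                          seed = NULL) {
  stopifnot(is.data.frame(baselines), "patient_id" %in% names(baselines),
            "arm" %in% names(baselines))
  baselines$patient_id <- as.character(baselines$patient_id)
  if (anyDuplicated(baselines$patient_id)) {
    dup <- baselines$patient_id[duplicated(baselines$patient_id)][1L]
    stop("duplicate patient_id '", dup, "' in baseline table")
  }
  bad <- setdiff(unique(baselines$arm), c("treatment", "control"))
  if (length(bad)) stop("unknown arm label(s): ", paste(bad, collapse = ", "))
  if (!is.null(events)) {
    events$patient_id <- as.character(events$patient_id)
    stopifnot(all(c("patient_id", "outcome", "time_days", "event") %in%
                    names(events)))
    orphan <- setdiff(events$patient_id, baselines$patient_id)
    if (length(orphan)) stop("event rows for unknown patient(s): ",
                             paste(utils::head(orphan, 3), collapse = ", "))
    key <- paste(events$patient_id, events$outcome)
    if (anyDuplicated(key))
      stop("more than one event record for (patient, outcome): ",
           key[duplicated(key)][1L])
  }
  structure(list(baselines = baselines, events = events,
                 provenance = provenance, seed = seed),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("<trial_dataset>", nrow(x$baselines), "patients (",
      sum(x$baselines$arm == "treatment"), "treatment /",
      sum(x$baselines$arm == "control"), "control ),",
      if (is.null(x$events)) 0L else nrow(x$events), "event records;",
      "provenance:", x$provenance, "\n")
  invisible(x)
}

#' Number of patients in a trial dataset
#' @param dataset a `trial_dataset`.
#' @return integer count.
#' @export
n_patients <- function(dataset) nrow(dataset$baselines)

# subset a trial dataset to a set of patient ids (keeps event rows aligned)
subset_patients <- function(dataset, ids) {
  b <- dataset$baselines[dataset$baselines$patient_id %in% ids, , drop = FALSE]
  e <- dataset$events
  if (!is.null(e)) e <- e[e$patient_id %in% ids, , drop = FALSE]
  trial_dataset(b, e, provenance = dataset$provenance, seed = dataset$seed)
}

# merged (time, event, treat) frame for one outcome
outcome_frame <- function(dataset, outcome) {
  stopifnot(!is.null(dataset$events))
  e <- dataset$events[dataset$events$outcome == outcome, , drop = FALSE]
  if (!nrow(e)) stop("no event records for outcome '", outcome, "'")
  i <- match(e$patient_id, dataset$baselines$patient_id)
  data.frame(patient_id = e$patient_id,
             time = as.numeric(e$time_days),
             event = as.integer(e$event),
             treat = as.integer(dataset$baselines$arm[i] == "treatment"),
             stringsAsFactors = FALSE)
}

.NUMERIC_BASELINE <- c("age", "edss", "relapses_2y", "disease_duration",
                       "t25fw_base", "hpt9_base", "sdmt_base", "gd_count",
                       "t2_volume", "cgm_volume", "thalamus_volume",
                       "gfap", "nfl")

#' Read a baseline table
#'
#' Reads a delimited baseline table (header row; empty cells or `"NA"` are
#' missing). Requires `patient_id`, `arm` and the clinical-practice columns;
#' optional tier columns are kept when present. Arm labels are mapped to
#' `treatment`/`control` through `arm_map`.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @param arm_map named character vector mapping file labels to canonical
#'   labels, e.g. `c(siponimod = "treatment", placebo = "control")`.
#' @return data frame of baseline profiles (one row per patient).
#' @export
read_baseline_table <- function(path, sep = ",",
                                arm_map = c(treatment = "treatment",
                                            control = "control")) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("patient_id", "arm", "age", "sex", "edss", "relapses_2y",
            "disease_duration")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("baseline table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$patient_id)) {
    dup <- df$patient_id[duplicated(df$patient_id)][1L]
    stop("duplicate patient_id '", dup, "'")
  }
  lab <- tolower(df$arm)
  bad <- which(!(lab %in% tolower(names(arm_map))) & !is.na(lab))
  if (length(bad))
    stop("unknown arm label '", df$arm[bad[1L]], "' at row ", bad[1L])
  df$arm <- unname(arm_map[match(lab, tolower(names(arm_map)))])
  for (col in intersect(.NUMERIC_BASELINE, names(df))) {
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      stop("non-numeric value '", raw[bad[1L]], "' in column '", col, "'")
    df[[col]] <- num
  }
  rownames(df) <- NULL
  df
}

#' Read an events table
#'
#' @param path CSV with columns `patient_id`, `outcome`, `time_days`, `event`.
#' @return data frame of progression events.
#' @export
read_events_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("patient_id", "outcome", "time_days", "event") %in%
                  names(df)))
  df$patient_id <- as.character(df$patient_id)
  df
}

# full-precision formatting so CSV round-trips are bit exact
.fmt_full <- function(x) {
  if (!is.numeric(x)) return(x)
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a trial dataset to a directory
#'
#' Writes `baselines.csv` and (when present) `events.csv` with numerics at
#' full precision, so [read_trial_dataset()] reproduces every value exactly.
#'
#' @param dataset a `trial_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  b <- dataset$baselines
  b[] <- lapply(b, .fmt_full)
  utils::write.csv(b, file.path(dir, "baselines.csv"), row.names = FALSE,
                   na = "NA", quote = FALSE)
  if (!is.null(dataset$events)) {
    e <- dataset$events
    e[] <- lapply(e, .fmt_full)
    utils::write.csv(e, file.path(dir, "events.csv"), row.names = FALSE,
                     na = "NA", quote = FALSE)
  }
  invisible(dir)
}

#' Read a trial dataset written by [write_trial_dataset()]
#' @param dir directory containing `baselines.csv` and optionally `events.csv`.
#' @param provenance label for the loaded dataset.
#' @return a `trial_dataset`.
#' @export
read_trial_dataset <- function(dir, provenance = dir) {
  if (!dir.exists(dir)) stop("dataset directory not found: ", dir)
  b <- read_baseline_table(file.path(dir, "baselines.csv"))
  ev_path <- file.path(dir, "events.csv")
  e <- if (file.exists(ev_path)) read_events_table(ev_path) else NULL
  trial_dataset(b, e, provenance = provenance)
}

#' Cohen's d balance statistic
#'
#' Standardized mean difference for continuous variables (pooled SD with
#' n-1 weights) or standardized proportion difference
#' (p_a - p_b) / sqrt(pbar (1 - pbar)) for binary ones. Absolute values above
#' 0.10 are flagged as meaningful imbalance.
#'
#' @param values_a,values_b numeric vectors (0/1 for `kind = "proportion"`).
#' @param kind `"continuous"` or `"proportion"`.
#' @param variable optional variable name carried into the result.
#' @return list with `variable`, `d`, and `flag` (`|d| > 0.10`).
#' @export
cohens_d <- function(values_a, values_b, kind = c("continuous", "proportion"),
                     variable = NA_character_) {
  kind <- match.arg(kind)
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (kind == "continuous") {
    if (length(a) < 2L || length(b) < 2L)
      stop("need at least 2 observations per group")
    sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
      (length(a) + length(b) - 2)
    if (sp2 <= 0) {
      if (isTRUE(all.equal(mean(a), mean(b)))) d <- 0
      else stop("zero pooled SD with unequal means: degenerate input")
    } else d <- (mean(a) - mean(b)) / sqrt(sp2)
  } else {
    pa <- mean(a); pb <- mean(b)
    pbar <- (sum(a) + sum(b)) / (length(a) + length(b))
    denom <- sqrt(pbar * (1 - pbar))
    if (denom == 0) {
      if (pa == pb) d <- 0
      else stop("degenerate proportions")
    } else d <- (pa - pb) / denom
  }
  list(variable = variable, d = d, flag = abs(d) > 0.10)
}

# balance table comparing train vs validation on every baseline variable
balance_table <- function(train_b, valid_b) {
  vars <- setdiff(names(train_b), c("patient_id"))
  rows <- lapply(vars, function(v) {
    xa <- train_b[[v]]; xb <- valid_b[[v]]
    if (v %in% c("arm", "sex")) {
      ref <- if (v == "arm") "treatment" else "male"
      r <- cohens_d(as.numeric(xa == ref), as.numeric(xb == ref),
                    "proportion", variable = v)
    } else if (is.numeric(xa)) {
      r <- tryCatch(cohens_d(xa, xb, "continuous", variable = v),
                    error = function(e) list(variable = v, d = NA_real_,
                                             flag = NA))
    } else return(NULL)
    data.frame(variable = r$variable, d = r$d, flag = r$flag)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Split a trial into training and validation sets
#'
#' Simple (unstratified) seeded random allocation. The training size is
#' `fraction * N` rounded half up, so a 70:30 split of 1,645 patients yields
#' 1,152 training and 493 validation patients. A Cohen's d balance table over
#' every baseline variable is attached.
#'
#' @param dataset a `trial_dataset`.
#' @param fraction training fraction in (0, 1); default 0.7.
#' @param seed integer RNG seed (recorded in the result).
#' @return list of class `split_result` with `train`, `validation`,
#'   `fraction`, `seed`, `balance`.
#' @export
split_train_validation <- function(dataset, fraction = 0.7, seed = 1L) {
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  n <- n_patients(dataset)
  if (n < 2L) stop("dataset too small to split")
  n_train <- as.integer(round_half_up(fraction * n, 0))
  ids <- dataset$baselines$patient_id
  set.seed(as.integer(seed))
  train_ids <- sample(ids, n_train)
  train <- subset_patients(dataset, train_ids)
  valid <- subset_patients(dataset, setdiff(ids, train_ids))
  structure(list(train = train, validation = valid, fraction = fraction,
                 seed = as.integer(seed),
                 balance = balance_table(train$baselines, valid$baselines)),
            class = "split_result")
}
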