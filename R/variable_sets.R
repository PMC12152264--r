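#' Covariate terms and variable sets
#'
#' Baseline covariates enter every model on a fixed transformed scale. Each
#' *term* names a baseline field plus its transform: `identity`, `log10`, or
#' the male indicator for sex. Disease duration and the GFAP/NfL biomarkers
#' are log10-transformed; all other fields enter untransformed.
#'
#' @name variable-sets
NULL

# term name -> (baseline field, transform)
.TERMS <- list(
  age                     = c("age", "identity"),
  male                    = c("sex", "male"),
  edss                    = c("edss", "identity"),
  relapses_2y             = c("relapses_2y", "identity"),
  log10_disease_duration  = c("disease_duration", "log10"),
  t25fw_base              = c("t25fw_base", "identity"),
  hpt9_base               = c("hpt9_base", "identity"),
  sdmt_base               = c("sdmt_base", "identity"),
  gd_count                = c("gd_count", "identity"),
  t2_volume               = c("t2_volume", "identity"),
  cgm_volume              = c("cgm_volume", "identity"),
  thalamus_volume         = c("thalamus_volume", "identity"),
  log10_gfap              = c("gfap", "log10"),
  log10_nfl               = c("nfl", "log10")
)

.TIER1 <- c("age", "male", "relapses_2y", "log10_disease_duration", "edss")
.TIER2 <- c(.TIER1, "t25fw_base", "hpt9_base", "sdmt_base")
.TIER3 <- c(.TIER2, "gd_count", "t2_volume")
.TIER4 <- c(.TIER3, "cgm_volume", "thalamus_volume", "log10_gfap", "log10_nfl")

#' Named baseline variable sets
#'
#' Returns the ordered term names of one of the four nested tiers of baseline
#' variables: routine clinical variables (`CLINICAL_PRACTICE`), plus the three
#' performance scores (`ADVANCED_CLINICAL`), plus routine MRI
#' (`CLINICAL_MRI`), plus research biomarkers (`EXPERIMENTAL`). Each tier is a
#' superset of the previous.
#'
#' @param name one of `"CLINICAL_PRACTICE"`, `"ADVANCED_CLINICAL"`,
#'   `"CLINICAL_MRI"`, `"EXPERIMENTAL"`.
#' @return character vector of term names usable wherever a covariate subset
#'   is expected.
#' @export
variable_set <- function(name = c("CLINICAL_PRACTICE", "ADVANCED_CLINICAL",
                                  "CLINICAL_MRI", "EXPERIMENTAL")) {
  switch(match.arg(name),
         CLINICAL_PRACTICE = .TIER1,
         ADVANCED_CLINICAL = .TIER2,
         CLINICAL_MRI = .TIER3,
         EXPERIMENTAL = .TIER4)
}

#' Transformed covariate matrix
#'
#' Builds the numeric design matrix of transformed covariates for the given
#' terms from a baseline table.
#'
#' @param baselines data frame of baseline profiles.
#' @param terms character vector of term names (see [variable_set()]).
#' @param allow_missing if `FALSE` (default), any missing value raises an
#'   error naming the offending variable.
#' @return numeric matrix, one column per term, rows aligned with `baselines`.
#' @export
covariate_matrix <- function(baselines, terms, allow_missing = FALSE) {
  unknown <- setdiff(terms, names(.TERMS))
  if (length(unknown)) stop("unknown covariate term(s): ",
                            paste(unknown, collapse = ", "))
  cols <- lapply(terms, function(tm) {
    def <- .TERMS[[tm]]
    field <- def[[1L]]
    if (!field %in% names(baselines))
      stop("baseline table lacks required variable '", field, "'")
    x <- baselines[[field]]
    v <- switch(def[[2L]],
                identity = as.numeric(x),
                log10 = log10(as.numeric(x)),
                male = as.numeric(tolower(as.character(x)) == "male"))
    if (!allow_missing && anyNA(v))
      stop("missing values in required variable '", field, "'")
    v
  })
  m <- do.call(cbind, cols)
  colnames(m) <- terms
  rownames(m) <- baselines$patient_id
  m
}
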