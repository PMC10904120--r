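## ---------------------------------------------------------------------------
## Cohort files: CSV, UTF-8, header row, one person per row.
## ---------------------------------------------------------------------------

cohort_schema <- function() {
  list(
    mandatory = c("person_id", "age_entry", "sex", "ethnicity", "smoking",
                  "bmi_category", "ldl", "hdl", "hba1c", "creatinine",
                  "sbp", "dbp", "treated_hypertension", "diabetes",
                  "diabetes_years", "cancer_history", CVD_HISTORY_FLAGS,
                  "severe_mental_illness", "physical_activity",
                  "diet_unhealthy", "townsend_quintile", "statin_at_entry"),
    optional = c("egfr", "albuminuria", "ten_year_cvd_risk"),
    levels = list(sex = SEX_LEVELS, ethnicity = ETHNICITY_LEVELS,
                  smoking = SMOKING_LEVELS, bmi_category = BMI_LEVELS,
                  diabetes = DIABETES_LEVELS, physical_activity = PA_LEVELS),
    flags = c("treated_hypertension", "cancer_history", CVD_HISTORY_FLAGS,
              "severe_mental_illness", "diet_unhealthy", "statin_at_entry",
              "albuminuria"),
    positive = c("ldl", "hdl", "hba1c", "creatinine", "sbp", "dbp")
  )
}

row_err <- function(rows, what) {
  cvd_error("cvd_validation_error",
            sprintf("row(s) %s: %s",
                    paste(utils::head(rows, 10), collapse = ","), what))
}

#' Validate a cohort of individual risk profiles
#'
#' Checks the full set of profile invariants: mandatory columns present,
#' category levels known, ages in (0, 110], deprivation quintile in 1..5,
#' biomarkers strictly positive, diabetes duration present and nonnegative
#' exactly when diabetes is present. Validation is total: malformed input
#' raises a classed error (`cvd_schema_error` / `cvd_validation_error`)
#' naming the offending column or rows; no partially validated object is
#' returned.
#'
#' @param df data frame of profiles, one person per row.
#' @return the validated data frame with class `cvd_cohort`, row numbers
#'   retained in attribute `source_row`.
#' @export
validate_cohort <- function(df) {
  sc <- cohort_schema()
  missing_cols <- setdiff(sc$mandatory, names(df))
  if (length(missing_cols)) {
    cvd_error("cvd_schema_error",
              paste0("missing mandatory column(s): ",
                     paste(missing_cols, collapse = ", ")))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$person_id <- as.character(df$person_id)
  if (anyDuplicated(df$person_id)) {
    row_err(which(duplicated(df$person_id)), "duplicate person_id")
  }
  for (col in sc$positive) {
    v <- as.numeric(df[[col]])
    bad <- which(!is.na(v) & v <= 0 | is.na(v))
    if (length(bad)) row_err(bad, sprintf("%s must be a positive number", col))
    df[[col]] <- v
  }
  age <- as.numeric(df$age_entry)
  bad <- which(is.na(age) | age <= 0 | age > AGE_CAP)
  if (length(bad)) row_err(bad, sprintf("age_entry must be in (0, %d]", AGE_CAP))
  df$age_entry <- age
  for (col in names(sc$levels)) {
    lv <- sc$levels[[col]]
    bad <- which(!(df[[col]] %in% lv))
    if (length(bad)) {
      row_err(bad, sprintf("%s has unknown level (allowed: %s)",
                           col, paste(lv, collapse = ", ")))
    }
    df[[col]] <- as.character(df[[col]])
  }
  for (col in intersect(c(sc$flags), names(df))) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) | !(v %in% c(0L, 1L)))
    if (length(bad)) row_err(bad, sprintf("%s must be 0 or 1", col))
    df[[col]] <- v
  }
  tq <- suppressWarnings(as.integer(df$townsend_quintile))
  bad <- which(is.na(tq) | !(tq %in% 1:5))
  if (length(bad)) row_err(bad, "townsend_quintile must be an integer in 1..5")
  df$townsend_quintile <- tq
  dy <- suppressWarnings(as.numeric(df$diabetes_years))
  has_d <- df$diabetes != "none"
  bad <- which(has_d & (is.na(dy) | dy < 0))
  if (length(bad)) row_err(bad, "diabetes_years must be >= 0 when diabetes present")
  bad <- which(!has_d & !is.na(dy))
  if (length(bad)) row_err(bad, "diabetes_years must be NA when diabetes absent")
  df$diabetes_years <- dy
  for (col in intersect(c("egfr", "ten_year_cvd_risk"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & (is.na(v) | v < 0))
    if (length(bad)) row_err(bad, sprintf("%s must be nonnegative", col))
    df[[col]] <- v
  }
  attr(df, "source_row") <- seq_len(nrow(df))
  class(df) <- c("cvd_cohort", "data.frame")
  df
}

#' Does each person have CVD history at entry?
#'
#' An empty entry CVD-history set routes a person to the primary-prevention
#' (`no_cvd`) risk equations; any prior MI, stroke, coronary
#' revascularisation, peripheral arterial disease or other coronary heart
#' disease routes to the secondary-prevention (`cvd`) equations.
#'
#' @param cohort validated cohort.
#' @return logical vector.
#' @export
has_cvd_history <- function(cohort) {
  rowSums(as.matrix(cohort[, CVD_HISTORY_FLAGS])) > 0
}

#' Read a cohort file
#'
#' Cohort files are UTF-8 CSV with a header row and one person per row; see
#' [validate_cohort()] for the schema and invariants enforced.
#'
#' @param path CSV file path.
#' @return validated `cvd_cohort` data frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""), fileEncoding = "UTF-8")
  validate_cohort(df)
}

#' Write a cohort file
#' @param cohort validated cohort.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   fileEncoding = "UTF-8", na = "NA")
  invisible(path)
}

## ---------------------------------------------------------------------------
## Reference population: CSV with columns sex, age_band, quintile, weight.
## ---------------------------------------------------------------------------

#' Construct a reference population weight table
#'
#' Weights over sex x age band x deprivation quintile cells used for direct
#' standardization of cohort summaries; normalized to sum to one.
#'
#' @param df data frame with columns `sex`, `age_band`, `quintile`, `weight`.
#' @return `reference_population` data frame, weights normalized.
#' @export
reference_population <- function(df) {
  need <- c("sex", "age_band", "quintile", "weight")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    cvd_error("cvd_schema_error",
              paste0("reference population missing column(s): ",
                     paste(miss, collapse = ", ")))
  }
  df <- as.data.frame(df)[need]
  df$sex <- as.character(df$sex)
  df$age_band <- as.character(df$age_band)
  df$quintile <- as.integer(df$quintile)
  df$weight <- as.numeric(df$weight)
  if (any(!(df$sex %in% SEX_LEVELS))) {
    cvd_error("cvd_validation_error", "reference population: unknown sex level")
  }
  if (any(is.na(df$weight) | df$weight < 0)) {
    cvd_error("cvd_validation_error",
              "reference population weights must be nonnegative")
  }
  if (any(!(df$quintile %in% 1:5))) {
    cvd_error("cvd_validation_error",
              "reference population quintile must be in 1..5")
  }
  tot <- sum(df$weight)
  if (tot <= 0) cvd_error("cvd_validation_error", "weights sum to zero")
  df$weight <- df$weight / tot
  class(df) <- c("reference_population", "data.frame")
  df
}

#' Read a reference-population weight table
#' @param path CSV with columns sex, age_band, quintile, weight.
#' @return `reference_population` data frame.
#' @export
read_reference_population <- function(path) {
  reference_population(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a reference-population weight table
#' @param ref `reference_population`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_reference_population <- function(ref, path) {
  utils::write.csv(as.data.frame(ref), path, row.names = FALSE)
  invisible(path)
}

#' Estimated glomerular filtration rate from serum creatinine
#'
#' CKD-EPI 2021 race-free creatinine equation. Used to derive eGFR for
#' treatment-eligibility rules when a cohort supplies creatinine but not eGFR;
#' the derivation is recorded in scenario output metadata.
#'
#' @param creatinine serum creatinine, umol/L.
#' @param age years.
#' @param sex `"male"` or `"female"`.
#' @return eGFR in mL/min/1.73m^2.
#' @export
egfr_ckdepi <- function(creatinine, age, sex) {
  scr <- creatinine / 88.4  # mg/dL
  female <- sex == "female"
  k <- ifelse(female, 0.7, 0.9)
  a <- ifelse(female, -0.241, -0.302)
  142 * pmin(scr / k, 1)^a * pmax(scr / k, 1)^(-1.200) *
    0.9938^age * ifelse(female, 1.012, 1)
}

cohort_egfr <- function(cohort) {
  if (!is.null(cohort$egfr) && !anyNA(cohort$egfr)) return(cohort$egfr)
  e <- egfr_ckdepi(cohort$creatinine, cohort$age_entry, cohort$sex)
  if (!is.null(cohort$egfr)) ifelse(is.na(cohort$egfr), e, cohort$egfr) else e
}
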