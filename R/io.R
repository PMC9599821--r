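COHORT_HEADER <- c("patient_id", "age", "sex", "deprivation", "ethnicity",
                   "comorbidity", "route", "follow_up_months", "dead",
                   "diagnosis_year")

#' Read and write patient-level cohorts as CSV
#'
#' The on-disk dictionary is: `patient_id` (unique), `age` (integer 45-99),
#' `sex` (`male`/`female`), `deprivation` (quintile 1 least - 5 most
#' deprived), `ethnicity` (`white`/`other`), `comorbidity` (0/1), `route`
#' (`elective`/`emergency`, empty field for missing), `follow_up_months`
#' (non-negative), `dead` (0/1), `diagnosis_year`. Headers are validated
#' strictly and malformed rows are rejected with their line numbers.
#'
#' @param path CSV file path.
#' @return `read_cohort()` returns a validated cohort data.frame (internal
#'   column `age_years`); `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop_medroute(sprintf("cohort file not found: %s", path), "medroute_io_error")
  }
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE),
    error = function(e) stop_medroute(
      sprintf("cannot parse cohort CSV %s: %s", path, conditionMessage(e)),
      "medroute_io_error")
  )
  if (!identical(names(raw), COHORT_HEADER)) {
    stop_medroute(sprintf(
      "unexpected cohort header: got [%s], expected [%s]",
      paste(names(raw), collapse = ","), paste(COHORT_HEADER, collapse = ",")),
      "medroute_io_error")
  }
  if (!nrow(raw)) stop_medroute("cohort file is empty", "medroute_io_error")
  line <- seq_len(nrow(raw)) + 1L # header is line 1
  bad <- function(rows, why) {
    stop_medroute(sprintf("invalid cohort rows (%s) at lines: %s", why,
                          paste(utils::head(line[rows], 10), collapse = ", ")),
                  "medroute_io_error")
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  age <- num(raw$age)
  if (any(is.na(age) | age < 45 | age > 99 | age != floor(age))) {
    bad(is.na(age) | age < 45 | age > 99 | age != floor(age),
        "age must be an integer in 45-99")
  }
  if (any(!raw$sex %in% c("male", "female"))) {
    bad(!raw$sex %in% c("male", "female"),
        sprintf("unknown sex level(s): %s",
                paste(unique(setdiff(raw$sex, c("male", "female"))), collapse = ",")))
  }
  dep <- num(raw$deprivation)
  if (any(is.na(dep) | !dep %in% 1:5)) bad(is.na(dep) | !dep %in% 1:5, "deprivation must be a quintile 1-5")
  if (any(!raw$ethnicity %in% c("white", "other"))) {
    bad(!raw$ethnicity %in% c("white", "other"),
        sprintf("unknown ethnicity level(s): %s",
                paste(unique(setdiff(raw$ethnicity, c("white", "other"))), collapse = ",")))
  }
  com <- num(raw$comorbidity)
  if (any(is.na(com) | !com %in% 0:1)) bad(is.na(com) | !com %in% 0:1, "comorbidity must be 0/1")
  route <- raw$route
  route[route == ""] <- NA_character_
  if (any(!is.na(route) & !route %in% c("elective", "emergency"))) {
    bad(!is.na(route) & !route %in% c("elective", "emergency"),
        sprintf("unknown route level(s): %s",
                paste(unique(setdiff(route[!is.na(route)], c("elective", "emergency"))), collapse = ",")))
  }
  fu <- num(raw$follow_up_months)
  if (any(is.na(fu) | fu < 0)) bad(is.na(fu) | fu < 0, "follow_up_months must be non-negative")
  dead <- num(raw$dead)
  if (any(is.na(dead) | !dead %in% 0:1)) bad(is.na(dead) | !dead %in% 0:1, "dead must be 0/1")
  year <- num(raw$diagnosis_year)
  if (any(is.na(year))) bad(is.na(year), "diagnosis_year must be numeric")
  if (anyDuplicated(raw$patient_id)) {
    stop_medroute("duplicate patient_id values in cohort", "medroute_io_error")
  }
  out <- data.frame(
    patient_id = raw$patient_id, age_years = as.integer(age), sex = raw$sex,
    deprivation = as.integer(dep), ethnicity = raw$ethnicity,
    comorbidity = as.integer(com), route = route, follow_up_months = fu,
    dead = as.integer(dead), diagnosis_year = as.integer(year),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cohort", "data.frame")
  out
}

#' @rdname read_cohort
#' @param cohort cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  out <- data.frame(
    patient_id = cohort$patient_id, age = cohort$age_years, sex = cohort$sex,
    deprivation = cohort$deprivation, ethnicity = cohort$ethnicity,
    comorbidity = cohort$comorbidity,
    route = ifelse(is.na(cohort$route), "", cohort$route),
    follow_up_months = cohort$follow_up_months, dead = cohort$dead,
    diagnosis_year = cohort$diagnosis_year, stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write life tables as CSV (`age,sex,year,rate`)
#'
#' @param path CSV path.
#' @return `read_life_table()` returns a validated `life_table` data.frame.
#' @export
read_life_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(x), c("age", "sex", "year", "rate"))) {
    stop_medroute("life-table CSV must have header age,sex,year,rate",
                  "medroute_io_error")
  }
  if (any(x$rate < 0)) stop_medroute("life-table rates must be non-negative", "medroute_io_error")
  class(x) <- c("life_table", "data.frame")
  x
}

#' @rdname read_life_table
#' @param lifetable life-table data.frame.
#' @export
write_life_table <- function(lifetable, path) {
  utils::write.csv(as.data.frame(lifetable), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
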