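## The long-format cohort container and its CSV readers/writers.
##
## A cohort is four tables keyed by stay_id:
##   stays        one row per ICU stay (statics + outcome)
##   measurements timestamped point values (glucose, labs, MAP, ...)
##   rates        interval-valued infusions (insulin, dextrose, vasopressor)
##   flags        on/off exposures (PN, EN, corticosteroids)
## Times are hours from ICU admission (decimal, 0-based, per-stay clock).

MEASUREMENT_VARIABLES <- c(
  "glucose_mgdl", "lactate_mmoll", "map_mmhg", "bilirubin_mgdl",
  "platelets_e3ul", "creatinine_mgdl", "pao2fio2", "gcs", "urine_mlh")

## Carry-forward horizon class per variable: "frequent" variables are
## carried at most 24 h, "infrequent" (daily labs) at most 48 h.
FREQUENT_VARIABLES <- c("glucose_mgdl", "lactate_mmoll", "map_mmhg")

DRUGS <- c("insulin", "dextrose", "vasopressor")
EXPOSURES <- c("parenteral_nutrition", "enteral_nutrition", "corticosteroids")

STAY_COLUMNS <- c("stay_id", "database", "hospital_id", "age_years", "sex",
                  "height_m", "weight_kg", "bmi", "admission_type",
                  "diabetes", "hba1c_pct", "los_icu_h", "hospital_mortality")

#' Construct a validated ICU cohort
#'
#' Assembles the four long-format tables into an `icu_cohort` object,
#' checking types, units and referential integrity. Stays without a BMI
#' (no recorded BMI and no height/weight to derive one) are excluded, and
#' BMI is (re)derived from height and weight whenever both are present.
#'
#' @param stays data.frame with columns `stay_id`, `database`,
#'   `hospital_id`, `age_years`, `sex` (male/female), `height_m`,
#'   `weight_kg`, `bmi`, `admission_type` (medical/surgical/other),
#'   `diabetes` (logical, may be NA), `hba1c_pct` (may be NA),
#'   `los_icu_h`, `hospital_mortality` (logical).
#' @param measurements data.frame with `stay_id`, `variable`, `time_h`,
#'   `value`. `variable` must be one of the supported measurement names.
#' @param rates data.frame with `stay_id`, `drug`, `start_h`, `end_h`,
#'   `rate`, `concentration_pct` (dextrose only), `bolus` (insulin only).
#' @param flags data.frame with `stay_id`, `exposure`, `start_h`, `end_h`.
#' @return An object of class `icu_cohort`: a list of the four
#'   data.tables, validated and keyed by stay.
#' @export
icu_cohort <- function(stays,
                       measurements = empty_measurements(),
                       rates = empty_rates(),
                       flags = empty_flags()) {
  stays <- data.table::as.data.table(stays)
  measurements <- data.table::as.data.table(measurements)
  rates <- data.table::as.data.table(rates)
  flags <- data.table::as.data.table(flags)

  require_columns(stays, STAY_COLUMNS, "stays")
  require_columns(measurements, c("stay_id", "variable", "time_h", "value"),
                  "measurements")
  require_columns(rates, c("stay_id", "drug", "start_h", "end_h", "rate",
                           "concentration_pct", "bolus"), "rates")
  require_columns(flags, c("stay_id", "exposure", "start_h", "end_h"), "flags")

  stays <- data.table::copy(stays)
  stays[, stay_id := as.character(stay_id)]
  stays[, diabetes := as.logical(diabetes)]
  stays[, hospital_mortality := as.logical(hospital_mortality)]
  for (num_col in c("age_years", "height_m", "weight_kg", "bmi",
                    "hba1c_pct", "los_icu_h")) {
    data.table::set(stays, j = num_col, value = as.numeric(stays[[num_col]]))
  }

  ## BMI: prefer height/weight-derived; fall back to recorded; drop stays
  ## with neither (mirrors inclusion criteria based on recorded BMI).
  derivable <- !is.na(stays$height_m) & !is.na(stays$weight_kg)
  stays[derivable, bmi := weight_kg / height_m^2]
  stays <- stays[!is.na(bmi)]

  validate_rows(stays, "stays", list(
    "duplicate stay_id" = duplicated(stays$stay_id),
    "age_years < 18" = !is.na(stays$age_years) & stays$age_years < 18,
    "sex not male/female" = !stays$sex %in% c("male", "female"),
    "admission_type invalid" =
      !stays$admission_type %in% c("medical", "surgical", "other"),
    "non-positive los_icu_h" =
      !is.finite(stays$los_icu_h) | stays$los_icu_h <= 0,
    "non-positive bmi" = !is.finite(stays$bmi) | stays$bmi <= 0,
    "hospital_mortality not logical" = is.na(stays$hospital_mortality)
  ))

  for (tb in list(measurements, rates, flags)) {
    tb[, stay_id := as.character(stay_id)]
  }
  rates[, bolus := as.logical(bolus)]
  for (num_col in c("start_h", "end_h", "rate", "concentration_pct")) {
    data.table::set(rates, j = num_col, value = as.numeric(rates[[num_col]]))
  }
  known <- stays$stay_id
  measurements <- measurements[stay_id %in% known]
  rates <- rates[stay_id %in% known]
  flags <- flags[stay_id %in% known]

  validate_rows(measurements, "measurements", list(
    "unknown variable" = !measurements$variable %in% MEASUREMENT_VARIABLES,
    "negative or non-finite time_h" =
      !is.finite(measurements$time_h) | measurements$time_h < 0,
    "non-finite value" = !is.finite(measurements$value),
    "non-positive glucose" = measurements$variable == "glucose_mgdl" &
      (!is.finite(measurements$value) | measurements$value <= 0),
    "duplicate (stay_id, variable, time_h)" =
      duplicated(measurements[, list(stay_id, variable, time_h)])
  ))

  validate_rows(rates, "rates", list(
    "unknown drug" = !rates$drug %in% DRUGS,
    "start_h > end_h" = rates$start_h > rates$end_h,
    "negative rate" = !is.finite(rates$rate) | rates$rate < 0,
    "negative start_h" = !is.finite(rates$start_h) | rates$start_h < 0,
    "dextrose without concentration" = rates$drug == "dextrose" &
      !is.finite(rates$concentration_pct)
  ))

  validate_rows(flags, "flags", list(
    "unknown exposure" = !flags$exposure %in% EXPOSURES,
    "start_h >= end_h" = flags$start_h >= flags$end_h,
    "negative start_h" = !is.finite(flags$start_h) | flags$start_h < 0
  ))

  los <- stays$los_icu_h
  names(los) <- stays$stay_id
  if (nrow(measurements) && any(measurements$time_h >
                                los[measurements$stay_id] + 1e-9)) {
    bad <- which(measurements$time_h > los[measurements$stay_id] + 1e-9)
    stop(sprintf(
      "measurements: %d row(s) with time_h after discharge (first: row %d)",
      length(bad), bad[1L]), call. = FALSE)
  }

  data.table::setkey(measurements, stay_id, variable, time_h)
  data.table::setkey(rates, stay_id, drug, start_h)
  data.table::setkey(flags, stay_id, exposure, start_h)

  structure(list(stays = stays, measurements = measurements,
                 rates = rates, flags = flags),
            class = "icu_cohort")
}

empty_measurements <- function() {
  data.table::data.table(stay_id = character(), variable = character(),
                         time_h = numeric(), value = numeric())
}

empty_rates <- function() {
  data.table::data.table(stay_id = character(), drug = character(),
                         start_h = numeric(), end_h = numeric(),
                         rate = numeric(), concentration_pct = numeric(),
                         bolus = logical())
}

empty_flags <- function() {
  data.table::data.table(stay_id = character(), exposure = character(),
                         start_h = numeric(), end_h = numeric())
}

require_columns <- function(tb, cols, name) {
  missing <- setdiff(cols, names(tb))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 name, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

## Raise an error naming the offending rows for the first failing check.
validate_rows <- function(tb, name, checks) {
  for (what in names(checks)) {
    bad <- which(checks[[what]])
    if (length(bad)) {
      shown <- paste(utils::head(bad, 5L), collapse = ", ")
      stop(sprintf("%s: %s in %d row(s) (rows: %s)",
                   name, what, length(bad), shown), call. = FALSE)
    }
  }
  invisible(tb)
}

#' @export
print.icu_cohort <- function(x, ...) {
  cat(sprintf(
    "<icu_cohort> %d stays | %d measurements | %d rate intervals | %d flags\n",
    nrow(x$stays), nrow(x$measurements), nrow(x$rates), nrow(x$flags)))
  cat("databases:", paste(sort(unique(x$stays$database)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read a cohort from its four CSV files
#'
#' Expects `stays.csv`, `measurements.csv`, `rates.csv` and `flags.csv`
#' (comma-separated, UTF-8, header row, '.' decimal mark) in `dir`, or an
#' explicit named list of paths. All validation of [icu_cohort()] applies;
#' offending rows are reported in the error message.
#'
#' @param dir Directory containing the four CSVs, or a named list/vector
#'   with entries `stays`, `measurements`, `rates`, `flags`.
#' @return An `icu_cohort`.
#' @export
read_cohort <- function(dir) {
  paths <- if (is.character(dir) && length(dir) == 1L && is.null(names(dir))) {
    file.path(dir, c(stays = "stays.csv", measurements = "measurements.csv",
                     rates = "rates.csv", flags = "flags.csv"))
  } else {
    unlist(dir)[c("stays", "measurements", "rates", "flags")]
  }
  names(paths) <- c("stays", "measurements", "rates", "flags")
  for (p in paths) {
    if (!file.exists(p)) stop("read_cohort: file not found: ", p,
                              call. = FALSE)
  }
  rd <- function(p, classes) {
    data.table::fread(p, colClasses = classes, na.strings = c("", "NA"))
  }
  icu_cohort(
    stays = rd(paths["stays"], list(
      character = c("stay_id", "database", "hospital_id", "sex",
                    "admission_type"),
      numeric = c("age_years", "height_m", "weight_kg", "bmi", "hba1c_pct",
                  "los_icu_h"),
      logical = c("diabetes", "hospital_mortality"))),
    measurements = rd(paths["measurements"], list(
      character = c("stay_id", "variable"),
      numeric = c("time_h", "value"))),
    rates = rd(paths["rates"], list(
      character = c("stay_id", "drug"),
      numeric = c("start_h", "end_h", "rate", "concentration_pct"),
      logical = "bolus")),
    flags = rd(paths["flags"], list(
      character = c("stay_id", "exposure"),
      numeric = c("start_h", "end_h"))))
}

#' Write a cohort to four CSV files
#'
#' Inverse of [read_cohort()]: writes `stays.csv`, `measurements.csv`,
#' `rates.csv` and `flags.csv` into `dir` (created if needed).
#'
#' @param cohort An `icu_cohort`.
#' @param dir Output directory.
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "icu_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("stays.csv", "measurements.csv", "rates.csv",
                            "flags.csv"))
  data.table::fwrite(cohort$stays, paths[1L])
  data.table::fwrite(cohort$measurements, paths[2L])
  data.table::fwrite(cohort$rates, paths[3L])
  data.table::fwrite(cohort$flags, paths[4L])
  invisible(paths)
}

## Per-stay glucose series (sorted), as a data.table(time_h, value).
glucose_series <- function(cohort, id) {
  m <- cohort$measurements
  m[list(id, "glucose_mgdl"), list(time_h, value), nomatch = NULL]
}
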