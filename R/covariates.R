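## Rule-based covariate engineering at arbitrary query times.
##
## Imputation policy: last observation carried forward, bounded by a
## per-class horizon (24 h for frequently measured variables: glucose,
## lactate, MAP; 48 h for daily labs), then cohort-median fallback.
## GCS defaults to 15 when never observed (unrecorded sedation-free
## patients) before any median fallback.

CARRY_HORIZON_H <- c(frequent = 24, infrequent = 48)

variable_class <- function(variable) {
  ifelse(variable %in% FREQUENT_VARIABLES, "frequent", "infrequent")
}

#' Value of a clinical time series at a query time
#'
#' Returns the last observation at or before `t` if its age does not
#' exceed the carry-forward horizon of the variable class (24 h for
#' `"frequent"`, 48 h for `"infrequent"`), otherwise the supplied cohort
#' median. Provenance is `"observed"` (measurement exactly at `t`),
#' `"carried"` or `"median"`.
#'
#' @param series data.frame with `time_h`, `value`, sorted by time.
#' @param t Query time in hours (>= 0).
#' @param class `"frequent"` or `"infrequent"`.
#' @param cohort_median Fallback value; required when carry-forward is
#'   exhausted.
#' @return List with `value` and `provenance`.
#' @export
value_at <- function(series, t, class = c("frequent", "infrequent"),
                     cohort_median = NA_real_) {
  class <- match.arg(class)
  stopifnot(t >= 0)
  series <- as_series(series)
  check_sorted(series$time_h)
  horizon <- CARRY_HORIZON_H[[class]]
  idx <- findInterval(t, series$time_h)
  if (idx >= 1L) {
    age <- t - series$time_h[idx]
    if (age <= horizon) {
      return(list(value = series$value[idx],
                  provenance = if (age == 0) "observed" else "carried"))
    }
  }
  if (!is.finite(cohort_median)) {
    stop("value_at: carry-forward exhausted and no cohort median available",
         call. = FALSE)
  }
  list(value = cohort_median, provenance = "median")
}

#' Shock flag at a query time
#'
#' Shock is defined as mean arterial pressure below 60 mmHg or any
#' vasopressor administration covering the query time.
#'
#' @param map_series MAP series (`time_h`, `value` in mmHg).
#' @param vasopressor_intervals data.frame with `start_h`, `end_h`.
#' @param t Query time (hours).
#' @param cohort_median_map Median MAP fallback for imputation.
#' @return Logical.
#' @export
shock_flag <- function(map_series, vasopressor_intervals, t,
                       cohort_median_map = 80) {
  on_pressor <- nrow(vasopressor_intervals) > 0 &&
    any(vasopressor_intervals$start_h <= t & t < vasopressor_intervals$end_h)
  if (on_pressor) return(TRUE)
  map <- value_at(map_series, t, class = "frequent",
                  cohort_median = cohort_median_map)$value
  map < 60
}

## Per-hour insulin dose profile: for hour bin (b-1, b] the dose is the
## sum of rates of infusions overlapping the bin plus all bolus units
## delivered in the bin. Bins are anchored at `anchor` (bin edges at
## anchor - k); for integer query times this is the absolute hour grid.
insulin_bin_doses <- function(intervals, bins_lo, bins_hi) {
  dose <- numeric(length(bins_lo))
  if (!nrow(intervals)) return(dose)
  inf <- intervals[!(intervals$bolus %in% TRUE), , drop = FALSE]
  bol <- intervals[intervals$bolus %in% TRUE, , drop = FALSE]
  for (k in seq_along(bins_lo)) {
    lo <- bins_lo[k]; hi <- bins_hi[k]
    if (nrow(inf)) {
      act <- inf$start_h < hi & inf$end_h > lo
      dose[k] <- dose[k] + sum(inf$rate[act])
    }
    if (nrow(bol)) {
      inb <- bol$start_h > lo & bol$start_h <= hi
      dose[k] <- dose[k] + sum(bol$rate[inb])
    }
  }
  dose
}

#' Maximum hourly insulin dose in the preceding 12 hours
#'
#' Maximum over the hourly bins covering `(t - 12, t]` of the infusion
#' rate active in the bin plus the total bolus units delivered in the
#' bin. Boluses are rows with `bolus = TRUE`, `start_h = end_h` and
#' `rate` holding the total units.
#'
#' @param insulin_intervals data.frame with `start_h`, `end_h`, `rate`,
#'   `bolus` for one stay's insulin orders.
#' @param t Query time (hours, >= 0).
#' @return Dose in u/h (0 when no insulin).
#' @export
max_insulin_12h <- function(insulin_intervals, t) {
  stopifnot(t >= 0)
  lo <- t - 12 + 0:11
  hi <- lo + 1
  max(0, insulin_bin_doses(insulin_intervals, lo, hi))
}

#' Dextrose infusion rate normalized to dextrose 10% equivalents
#'
#' Sums, over intervals active at `t`, `rate * concentration_pct / 10`.
#' Dextrose 5% is excluded by convention; concentrations other than
#' 5/10/20/50 raise an error.
#'
#' @param dextrose_intervals data.frame with `start_h`, `end_h`, `rate`
#'   (mL/h), `concentration_pct`.
#' @param t Query time (hours).
#' @return Equivalent D10 rate in mL/h.
#' @export
dextrose_d10_rate <- function(dextrose_intervals, t) {
  if (!nrow(dextrose_intervals)) return(0)
  conc <- dextrose_intervals$concentration_pct
  if (any(!conc %in% c(5, 10, 20, 50))) {
    stop("dextrose_d10_rate: unknown dextrose concentration", call. = FALSE)
  }
  act <- dextrose_intervals$start_h <= t & t < dextrose_intervals$end_h &
    conc != 5
  sum(dextrose_intervals$rate[act] * conc[act] / 10)
}

## Standard SOFA component thresholds (original consensus definition).
## The cardiovascular component uses MAP and a generic vasopressor flag:
## any vasopressor scores 2 (lowest qualifying dose band) because the
## minimal schema does not carry drug-specific doses.
sofa_respiratory <- function(pf) {
  ifelse(pf < 100, 4L, ifelse(pf < 200, 3L, ifelse(pf < 300, 2L,
    ifelse(pf < 400, 1L, 0L))))
}
sofa_coagulation <- function(plt) {
  ifelse(plt < 20, 4L, ifelse(plt < 50, 3L, ifelse(plt < 100, 2L,
    ifelse(plt < 150, 1L, 0L))))
}
sofa_hepatic <- function(bili) {
  ifelse(bili >= 12, 4L, ifelse(bili >= 6, 3L, ifelse(bili >= 2, 2L,
    ifelse(bili >= 1.2, 1L, 0L))))
}
sofa_cardiovascular <- function(map, on_pressor) {
  ifelse(on_pressor, 2L, ifelse(map < 70, 1L, 0L))
}
sofa_cns <- function(gcs) {
  ifelse(gcs < 6, 4L, ifelse(gcs <= 9, 3L, ifelse(gcs <= 12, 2L,
    ifelse(gcs <= 14, 1L, 0L))))
}
sofa_renal <- function(creat) {
  ifelse(creat >= 5, 4L, ifelse(creat >= 3.5, 3L, ifelse(creat >= 2, 2L,
    ifelse(creat >= 1.2, 1L, 0L))))
}

#' Hourly SOFA components for one stay at a query time
#'
#' Applies the standard SOFA thresholds to values obtained via
#' [value_at()] (labs carried up to 48 h, MAP up to 24 h, then cohort
#' medians; GCS defaults to 15 when never observed). The cardiovascular
#' component scores 2 for any vasopressor administration.
#'
#' @param stay_measurements The stay's measurement rows (long format).
#' @param vasopressor_intervals The stay's vasopressor intervals.
#' @param t Query time (hours).
#' @param cohort_medians Named vector of per-variable fallback medians.
#' @return List of the six components plus `total` and `no_cardio`.
#' @export
sofa_components <- function(stay_measurements, vasopressor_intervals, t,
                            cohort_medians) {
  get <- function(var, default = NA_real_) {
    s <- stay_measurements[stay_measurements$variable == var, , drop = FALSE]
    med <- if (is.finite(default)) default else cohort_medians[[var]]
    if (is.null(med) || !is.finite(med)) med <- default
    if (!nrow(s)) {
      if (!is.finite(med)) stop("sofa_components: no value for ", var,
                                call. = FALSE)
      return(med)
    }
    value_at(s[order(s$time_h), c("time_h", "value")], t,
             class = variable_class(var), cohort_median = med)$value
  }
  on_pressor <- nrow(vasopressor_intervals) > 0 &&
    any(vasopressor_intervals$start_h <= t & t < vasopressor_intervals$end_h)
  comp <- list(
    respiratory = sofa_respiratory(get("pao2fio2")),
    coagulation = sofa_coagulation(get("platelets_e3ul")),
    hepatic = sofa_hepatic(get("bilirubin_mgdl")),
    cardiovascular = sofa_cardiovascular(get("map_mmhg"), on_pressor),
    cns = sofa_cns(get("gcs", default = 15)),
    renal = sofa_renal(get("creatinine_mgdl")))
  comp$total <- sum(unlist(comp))
  comp$no_cardio <- comp$total - comp$cardiovascular
  comp
}

#' Per-database imputation medians
#'
#' Median of all observed values per variable, computed separately per
#' database (pooled across databases as fallback for variables a
#' database never measures).
#'
#' @param cohort An `icu_cohort`.
#' @return data.table with columns `database`, `variable`, `med`.
#' @export
cohort_medians <- function(cohort) {
  m <- cohort$measurements[cohort$stays[, list(stay_id, database)],
                           on = "stay_id", nomatch = NULL]
  per_db <- m[, list(med = stats::median(value)), by = list(database, variable)]
  pooled <- m[, list(med = stats::median(value)), by = variable]
  grid <- data.table::CJ(database = unique(cohort$stays$database),
                         variable = unique(m$variable))
  out <- per_db[grid, on = c("database", "variable")]
  out[pooled, med_pooled := i.med, on = "variable"]
  out[is.na(med), med := med_pooled]
  out[, med_pooled := NULL]
  out[]
}

#' Assemble the full covariate vector for one stay at a query time
#'
#' @param cohort An `icu_cohort`.
#' @param id Stay identifier.
#' @param t Query time (hours, >= 0).
#' @param medians Optional precomputed [cohort_medians()] table.
#' @return One-row data.table with glucose, lactate, shock, insulin,
#'   dextrose, nutrition/steroid flags and SOFA fields.
#' @export
covariate_vector <- function(cohort, id, t, medians = NULL) {
  stopifnot(inherits(cohort, "icu_cohort"), t >= 0)
  if (is.null(medians)) medians <- cohort_medians(cohort)
  db <- cohort$stays[stay_id == id, database]
  med <- medians[database == db]
  medv <- stats::setNames(med$med, med$variable)
  sm <- cohort$measurements[stay_id == id]
  sr <- cohort$rates[stay_id == id]
  sf <- cohort$flags[stay_id == id]
  vaso <- sr[drug == "vasopressor"]

  series_of <- function(var) sm[variable == var, list(time_h, value)]
  glu <- value_at(series_of("glucose_mgdl"), t, "frequent",
                  medv[["glucose_mgdl"]])
  lac <- value_at(series_of("lactate_mmoll"), t, "frequent",
                  medv[["lactate_mmoll"]])
  sofa <- sofa_components(sm, vaso, t, as.list(medv))
  covers <- function(tb) nrow(tb) > 0 && any(tb$start_h <= t & t < tb$end_h)
  data.table::data.table(
    stay_id = id, time_h = t,
    glucose_mgdl = glu$value, glucose_provenance = glu$provenance,
    lactate_mmoll = lac$value, lactate_provenance = lac$provenance,
    shock = shock_flag(series_of("map_mmhg"), vaso, t,
                       medv[["map_mmhg"]]),
    insulin_max12_uh = max_insulin_12h(sr[drug == "insulin"], t),
    dextrose_d10_mlh = dextrose_d10_rate(sr[drug == "dextrose"], t),
    pn = covers(sf[exposure == "parenteral_nutrition"]),
    en = covers(sf[exposure == "enteral_nutrition"]),
    steroids = covers(sf[exposure == "corticosteroids"]),
    sofa_total = sofa$total,
    sofa_cardio = sofa$cardiovascular,
    sofa_no_cardio = sofa$no_cardio)
}

#' Missingness of key variables at a query time
#'
#' Fraction of stays, per variable and BMI group, with no observation
#' usable at time `t` before imputation: no measurement in
#' `[t - horizon, t]` where the horizon is the variable's carry-forward
#' bound (and no measurement at all counts as missing).
#'
#' @param cohort An `icu_cohort`.
#' @param t Query time in hours (default 24).
#' @param variables Variables to report (default: all measured ones).
#' @return data.table with `variable`, `bmi_group`, `n`, `missing_frac`.
#' @export
missingness_report <- function(cohort, t = 24,
                               variables = MEASUREMENT_VARIABLES) {
  stays <- data.table::copy(cohort$stays)
  stays[, bmi_group := assign_bmi_group(bmi)]
  m <- cohort$measurements[variable %in% variables]
  grid <- data.table::CJ(stay_id = stays$stay_id, variable = variables)
  usable <- m[, list(usable = any(time_h <= t &
                                  time_h >= t - CARRY_HORIZON_H[[
                                    variable_class(variable[1L])]])),
              by = list(stay_id, variable)]
  grid[usable, usable := i.usable, on = c("stay_id", "variable")]
  grid[is.na(usable), usable := FALSE]
  grid[stays, bmi_group := i.bmi_group, on = "stay_id"]
  grid[, list(n = .N, missing_frac = mean(!usable)),
       by = list(variable, bmi_group)][order(variable, bmi_group)]
}
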