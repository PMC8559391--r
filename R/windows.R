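## Discrete-time 6-hour-window dataset.
##
## Feature times are 6, 12, 18, ... h into the stay; the outcome window
## of the record at feature time t is (t, t + 6]. H = 1 for the record
## whose outcome window contains the first hypoglycemia onset; all later
## windows are censored. A stay whose first onset precedes (or equals)
## the first feature time contributes no records. Partial terminal
## windows before discharge are retained with H = 0.

#' Discrete-time window skeleton for one stay
#'
#' @param stay One-row data.frame/list with `stay_id` and `los_icu_h`.
#' @param episodes An `episode_set` from [build_episodes()] (its
#'   `first_onset_h` attribute drives censoring), or a plain number
#'   giving the first onset time (NA for none).
#' @param window_h Window length in hours (default 6).
#' @return data.table with `stay_id`, `feature_time_h`, `H`.
#' @export
build_windows <- function(stay, episodes, window_h = 6) {
  onset <- if (is.numeric(episodes)) {
    episodes
  } else {
    attr(episodes, "first_onset_h")
  }
  if (is.null(onset) || length(onset) == 0L) onset <- NA_real_
  lim <- min(stay$los_icu_h, onset, na.rm = TRUE)
  n <- max(0L, ceiling(lim / window_h) - 1L)
  ft <- window_h * seq_len(n)
  ft <- ft[ft < lim]
  data.table::data.table(
    stay_id = rep(stay$stay_id, length(ft)),
    feature_time_h = ft,
    H = as.integer(!is.na(onset) & onset > ft & onset <= ft + window_h))
}

#' Bin a covariate vector to the model's categorical levels
#'
#' Maps the continuous fields of a [covariate_vector()] row to the
#' analysis bins: glucose \[70,108)/\[108,144)/\[144,180)/>=180 mg/dL,
#' insulin 0/(0,2.5\]/(2.5,5\]/>5 u/h, lactate \[0,2)/\[2,5)/>=5 mmol/L,
#' dextrose-10% 0/(0,25)/>=25 mL/h. A glucose value below 70 at a
#' feature time (impossible under censoring with matching thresholds) is
#' assigned to the referent bin with a warning.
#'
#' @param vector One-row data.frame from [covariate_vector()].
#' @return The row with `glucose_bin`, `insulin_bin`, `lactate_bin`,
#'   `dextrose_bin` columns added.
#' @export
bin_covariates <- function(vector) {
  out <- data.table::as.data.table(vector)
  if (any(out$glucose_mgdl < 70)) {
    warning("glucose below 70 mg/dL at a feature time; assigned to the ",
            "referent bin", call. = FALSE)
    out[glucose_mgdl < 70, glucose_mgdl := 70]
  }
  out[, glucose_bin := bin_glucose(glucose_mgdl)]
  out[, insulin_bin := bin_insulin(insulin_max12_uh)]
  out[, lactate_bin := bin_lactate(lactate_mmoll)]
  out[, dextrose_bin := bin_dextrose(dextrose_d10_mlh)]
  out[]
}

#' Exclude low-insulin-prevalence hospitals
#'
#' Removes stays belonging to hospitals where strictly fewer than
#' `min_insulin_prevalence` of stays received any insulin. The filter is
#' restricted to multi-hospital sites (by default, databases with more
#' than one hospital id), emulating the underreporting guard applied to
#' a multi-center collection.
#'
#' @param cohort An `icu_cohort`.
#' @param min_insulin_prevalence Exclusion threshold (default 0.20,
#'   strict `<`).
#' @param sites Databases the filter applies to; default: all databases
#'   with more than one distinct `hospital_id`.
#' @return Filtered `icu_cohort`.
#' @export
filter_hospitals <- function(cohort, min_insulin_prevalence = 0.20,
                             sites = NULL) {
  stays <- cohort$stays
  if (is.null(sites)) {
    nh <- stays[, list(nh = data.table::uniqueN(hospital_id)), by = database]
    sites <- nh[nh > 1L, database]
  }
  if (!length(sites)) return(cohort)
  has_insulin <- unique(cohort$rates[drug == "insulin", stay_id])
  prev <- stays[, list(prevalence = mean(stay_id %in% has_insulin)),
                by = list(database, hospital_id)]
  drop <- prev[database %in% sites & prevalence < min_insulin_prevalence]
  keep_ids <- stays[!drop, on = c("database", "hospital_id"), stay_id]
  icu_cohort(stays = stays[stay_id %in% keep_ids],
             measurements = cohort$measurements[stay_id %in% keep_ids],
             rates = cohort$rates[stay_id %in% keep_ids],
             flags = cohort$flags[stay_id %in% keep_ids])
}

## Vectorized covariate table at all candidate feature times of every
## stay (before censoring). This is the single code path producing the
## design-matrix covariates, used both by the fitting pipeline and by
## the synthetic generator when it applies the ground-truth hazard, so
## that parameter recovery is not biased by feature-engineering drift.
window_feature_table <- function(cohort, window_h = 6, medians = NULL) {
  stays <- cohort$stays
  if (is.null(medians)) medians <- cohort_medians(cohort)

  k <- pmax(0L, ceiling(stays$los_icu_h / window_h) - 1L)
  idx <- rep.int(seq_len(nrow(stays)), k)
  W <- data.table::data.table(
    stay_id = stays$stay_id[idx],
    database = stays$database[idx],
    feature_time_h = window_h * unlist(lapply(k, seq_len), use.names = FALSE))
  W <- W[feature_time_h < stays$los_icu_h[idx]]
  data.table::setkey(W, stay_id, feature_time_h)

  med_of <- function(var) {
    m <- medians[variable == var]
    stats::setNames(m$med, m$database)[W$database]
  }
  ## one rolling join for all variables at once; split blocks afterwards
  need_vars <- c("glucose_mgdl", "lactate_mmoll", "map_mmhg", "pao2fio2",
                 "platelets_e3ul", "bilirubin_mgdl", "gcs",
                 "creatinine_mgdl")
  nW <- nrow(W)
  qry <- data.table::data.table(
    stay_id = rep(W$stay_id, length(need_vars)),
    variable = rep(need_vars, each = nW),
    time_h = rep(W$feature_time_h, length(need_vars)))
  hit <- cohort$measurements[qry,
                             on = c("stay_id", "variable", "time_h"),
                             roll = TRUE,
                             list(obs_t = x.time_h, value = x.value)]
  last_obs <- function(var, horizon, fallback = NULL) {
    blk <- (match(var, need_vars) - 1L) * nW + seq_len(nW)
    val <- hit$value[blk]
    age <- W$feature_time_h - hit$obs_t[blk]
    stale <- is.na(val) | age > horizon
    if (any(stale)) {
      fb <- if (is.null(fallback)) med_of(var) else rep(fallback, nW)
      val[stale] <- fb[stale]
    }
    val
  }
  covers_any <- function(tb) {
    if (!nrow(tb)) return(rep(FALSE, nrow(W)))
    hit <- tb[W, on = c("stay_id", "start_h<=feature_time_h",
                        "end_h>feature_time_h"),
              list(hit = !is.na(x.start_h[1L])), by = .EACHI]
    hit$hit
  }

  W[, glucose_mgdl := last_obs("glucose_mgdl", CARRY_HORIZON_H["frequent"])]
  W[, lactate_mmoll := last_obs("lactate_mmoll", CARRY_HORIZON_H["frequent"])]
  map <- last_obs("map_mmhg", CARRY_HORIZON_H["frequent"])
  vaso <- cohort$rates[drug == "vasopressor"]
  on_pressor <- covers_any(vaso)
  W[, shock := on_pressor | map < 60]

  ## insulin: max hourly bin dose over (t-12, t]
  ins <- cohort$rates[drug == "insulin"]
  W[, insulin_max12_uh := 0]
  if (nrow(ins)) {
    inf <- ins[!(bolus %in% TRUE)]
    bol <- ins[bolus %in% TRUE]
    ## hour bins are only needed for windows of stays with any insulin
    wtab <- data.table::data.table(stay_id = W$stay_id,
                                   feature_time_h = W$feature_time_h,
                                   wid = seq_len(nrow(W)))
    bins <- wtab[stay_id %in% unique(ins$stay_id)][
      , list(lo = feature_time_h - 12 + 0:11), by = list(stay_id, wid)]
    bins[, hi := lo + 1]
    dose <- rep(0, nrow(bins))
    if (nrow(inf)) {
      ov <- inf[bins, on = c("stay_id", "start_h<hi", "end_h>lo"),
                list(d = sum(x.rate, na.rm = TRUE)), by = .EACHI]
      dose <- dose + ifelse(is.na(ov$d), 0, ov$d)
    }
    if (nrow(bol)) {
      bv <- bol[bins, on = c("stay_id", "start_h>lo", "start_h<=hi"),
                list(d = sum(x.rate, na.rm = TRUE)), by = .EACHI]
      dose <- dose + ifelse(is.na(bv$d), 0, bv$d)
    }
    bins[, dose := dose]
    mx <- bins[, list(m = max(dose)), by = wid]
    W[mx$wid, insulin_max12_uh := pmax(0, mx$m)]
  }

  ## dextrose: D10-equivalent rate of intervals active at t (D5 excluded)
  dex <- cohort$rates[drug == "dextrose" & concentration_pct != 5]
  W[, dextrose_d10_mlh := 0]
  if (nrow(dex)) {
    dv <- dex[W, on = c("stay_id", "start_h<=feature_time_h",
                        "end_h>feature_time_h"),
              list(d = sum(x.rate * x.concentration_pct / 10, na.rm = TRUE)),
              by = .EACHI]
    W[, dextrose_d10_mlh := ifelse(is.na(dv$d), 0, dv$d)]
  }

  W[, pn := covers_any(cohort$flags[exposure == "parenteral_nutrition"])]
  W[, en := covers_any(cohort$flags[exposure == "enteral_nutrition"])]
  W[, steroids := covers_any(cohort$flags[exposure == "corticosteroids"])]

  h48 <- CARRY_HORIZON_H["infrequent"]
  resp <- sofa_respiratory(last_obs("pao2fio2", h48))
  coag <- sofa_coagulation(last_obs("platelets_e3ul", h48))
  hep <- sofa_hepatic(last_obs("bilirubin_mgdl", h48))
  cardio <- sofa_cardiovascular(map, on_pressor)
  cns <- sofa_cns(last_obs("gcs", h48, fallback = 15))
  renal <- sofa_renal(last_obs("creatinine_mgdl", h48))
  W[, sofa_no_cardio := resp + coag + hep + cns + renal]
  W[, sofa_total := sofa_no_cardio + cardio]

  st <- stays[, list(stay_id, bmi, weight_kg, admission_type, diabetes,
                     hospital_id)]
  W[st, `:=`(bmi_group = assign_bmi_group(i.bmi), diabetes = i.diabetes,
             hospital_id = i.hospital_id), on = "stay_id"]
  W[]
}

## Attach bins and the H outcome (censoring at first onset).
design_records <- function(cohort, window_h = 6, medians = NULL,
                           threshold = HYPO_THRESHOLD_MGDL) {
  W <- window_feature_table(cohort, window_h = window_h, medians = medians)
  onset <- cohort$measurements[variable == "glucose_mgdl" &
                               value <= threshold,
                               list(onset = min(time_h)), by = stay_id]
  W[onset, onset := i.onset, on = "stay_id"]
  lim <- cohort$stays[, list(stay_id, los_icu_h)]
  W[lim, los := i.los_icu_h, on = "stay_id"]
  W <- W[is.na(onset) | feature_time_h < onset]
  W[, H := as.integer(!is.na(onset) & onset > feature_time_h &
                      onset <= feature_time_h + window_h)]
  W[, glucose_bin := bin_glucose(pmax(glucose_mgdl, 70))]
  W[, insulin_bin := bin_insulin(insulin_max12_uh)]
  W[, lactate_bin := bin_lactate(lactate_mmoll)]
  W[, dextrose_bin := bin_dextrose(dextrose_d10_mlh)]
  W[, c("onset", "los") := NULL]
  W[]
}

#' Assemble the pooled design table for the discrete-time hazard model
#'
#' Builds every stay's window records (censored at first hypoglycemia),
#' attaches the binned covariates and the database indicator, and
#' optionally restricts to the low-missingness subset or adds the
#' diabetes adjustment column.
#'
#' @param cohort An `icu_cohort` (after [filter_hospitals()] when the
#'   insulin-prevalence guard is wanted).
#' @param window_h Window length in hours (default 6).
#' @param adjust_diabetes If TRUE, restrict to databases carrying the
#'   diabetes flag and include `diabetes` as a predictor.
#' @param subset `"all"` or `"low_missingness"` (keeps databases whose
#'   lactate missingness at 24 h is below `lactate_missing_cap`; BMI is
#'   complete by construction after loading).
#' @param lactate_missing_cap Cap for the low-missingness subset
#'   (default 0.15).
#' @param threshold Hypoglycemia threshold in mg/dL.
#' @return A `design_table`: data.table of window records with attribute
#'   `referents` naming the referent level of every categorical term.
#' @export
assemble_design <- function(cohort, window_h = 6, adjust_diabetes = FALSE,
                            subset = c("all", "low_missingness"),
                            lactate_missing_cap = 0.15,
                            threshold = HYPO_THRESHOLD_MGDL) {
  subset <- match.arg(subset)
  stopifnot(inherits(cohort, "icu_cohort"))
  if (subset == "low_missingness") {
    ## databases where the fraction of stays with no lactate usable at
    ## 24 h (observation in [0, 24]) is below the cap; BMI is complete
    ## by construction after loading, so only the lactate cap binds
    usable <- unique(cohort$measurements[variable == "lactate_mmoll" &
                                         time_h <= 24, stay_id])
    frac <- cohort$stays[, list(miss = mean(!stay_id %in% usable)),
                         by = database]
    keep_db <- frac[miss < lactate_missing_cap, database]
    ids <- cohort$stays[database %in% keep_db, stay_id]
    cohort <- icu_cohort(cohort$stays[stay_id %in% ids],
                         cohort$measurements[stay_id %in% ids],
                         cohort$rates[stay_id %in% ids],
                         cohort$flags[stay_id %in% ids])
  }
  rec <- design_records(cohort, window_h = window_h, threshold = threshold)
  site_levels <- sort(unique(cohort$stays$database))
  rec[, database := factor(database, levels = site_levels)]
  if (adjust_diabetes) {
    carriers <- cohort$stays[, list(has = any(!is.na(diabetes))),
                             by = database][has == TRUE, database]
    if (!length(carriers)) {
      stop("assemble_design: adjust_diabetes requested but no database ",
           "carries the diabetes flag", call. = FALSE)
    }
    rec <- rec[database %in% carriers & !is.na(diabetes)]
    rec[, database := droplevels(database)]
  } else {
    rec[, diabetes := NULL]
  }
  referents <- c(bmi_group = "[18.5,25)", glucose_bin = "[70,108)",
                 insulin_bin = "0", lactate_bin = "[0,2)",
                 dextrose_bin = "0", database = levels(rec$database)[1L])
  structure(rec, class = c("design_table", class(rec)),
            referents = referents, window_h = window_h)
}

#' @export
print.design_table <- function(x, ...) {
  cat(sprintf("<design_table> %d window records | %d stays | %d events\n",
              nrow(x), data.table::uniqueN(x$stay_id), sum(x$H)))
  invisible(x)
}
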