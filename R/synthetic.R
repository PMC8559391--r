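## Synthetic ICU-cohort generator with known ground truth.
##
## The generator emulates the statistical structure the analysis
## assumes: BMI-group mix matching a large teaching-hospital cohort,
## irregular glucose sampling (renewal process, mean gap ~4 h),
## AR(1) latent glucose around a BMI-by-diabetes group mean,
## hypoglycemia drawn per 6-h window from a logistic hazard applied to
## the *binned* covariates (exactly the design matrix the fitter sees,
## so parameter recovery is not confounded by binning error), and
## mortality driven by BMI group and hypoglycemia occurrence.
## Non-event glucose is floored just above the hypoglycemia threshold:
## every hypoglycemic measurement is hazard-driven, which is what makes
## the ground-truth coefficients recoverable.

#' Configuration for the synthetic cohort generator
#'
#' All defaults constitute the package's reference scenario: four site
#' labels standing in for the real multi-database setting (one of them
#' multi-hospital), BMI-group proportions (3, 31, 34, 18, 7, 6)/99,
#' monotone-decreasing BMI hazard effects and treatment/physiology
#' rules described in the methods vignette.
#'
#' @param n_stays Number of ICU stays.
#' @param seed Integer seed (NULL: use the ambient RNG state).
#' @param bmi_group_probs Six probabilities summing to 1.
#' @param hazard_beta Named log-odds vector on the model's bin scale;
#'   names follow the design-matrix convention (`"bmi_group=[25,30)"`,
#'   `"shock"`, `"sofa_no_cardio"`, `"database=eicu"`, ...). Missing
#'   names mean 0.
#' @param mortality_beta Named vector: `"(Intercept)"`, BMI-group
#'   effects and `"any_hypo"`.
#' @param mean_glucose_by_group 6 x 2 matrix of latent glucose means
#'   (rows: BMI groups; columns: non-diabetic, diabetic), mg/dL.
#' @param glucose_sd,glucose_ar1 Stationary SD (mg/dL) and AR(1)
#'   coefficient of latent glucose at successive measurements.
#' @param measurement_gap_mean_h Mean glucose inter-measurement gap (h).
#' @param los_mean_h Mean ICU length of stay (h), must exceed 12.
#' @param site_labels,site_probs,site_intercepts,n_hospitals Database
#'   analogs, their mixing proportions, per-site hazard intercept
#'   shifts and hospital counts.
#' @param treatment_rules List of probabilities/parameters linking
#'   insulin, dextrose, nutrition, steroid and vasopressor generation
#'   to glucose and severity; see the vignette.
#' @param hazard_scale `"binned"` (default) applies the hazard on the
#'   fitted bin scale; `"continuous"` applies a linear hazard on raw
#'   covariates (`continuous_beta`) to study binning misspecification.
#' @param continuous_beta Named per-unit log-odds used when
#'   `hazard_scale = "continuous"`.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(
    n_stays = 2000,
    seed = NULL,
    bmi_group_probs = c(3, 31, 34, 18, 7, 6) / 99,
    hazard_beta = default_hazard_beta(),
    mortality_beta = default_mortality_beta(),
    mean_glucose_by_group = cbind(nondiabetic = c(125, 130, 135, 140, 145, 150),
                                  diabetic = c(150, 155, 160, 165, 170, 175)),
    glucose_sd = 30,
    glucose_ar1 = 0.7,
    measurement_gap_mean_h = 4,
    los_mean_h = 72,
    site_labels = c("aumc", "hirid", "mimic", "eicu"),
    site_probs = c(0.085, 0.12, 0.095, 0.70),
    site_intercepts = c(aumc = 0, hirid = log(0.43), mimic = log(0.92),
                        eicu = log(1.51)),
    n_hospitals = c(aumc = 1, hirid = 1, mimic = 1, eicu = 10),
    diabetes_prob = c(0.10, 0.15, 0.20, 0.28, 0.35, 0.40),
    treatment_rules = default_treatment_rules(),
    hazard_scale = c("binned", "continuous"),
    continuous_beta = default_continuous_beta()) {
  hazard_scale <- match.arg(hazard_scale)
  cfg <- list(n_stays = n_stays, seed = seed,
              bmi_group_probs = bmi_group_probs, hazard_beta = hazard_beta,
              mortality_beta = mortality_beta,
              mean_glucose_by_group = mean_glucose_by_group,
              glucose_sd = glucose_sd, glucose_ar1 = glucose_ar1,
              measurement_gap_mean_h = measurement_gap_mean_h,
              los_mean_h = los_mean_h, site_labels = site_labels,
              site_probs = site_probs, site_intercepts = site_intercepts,
              n_hospitals = n_hospitals, diabetes_prob = diabetes_prob,
              treatment_rules = treatment_rules,
              hazard_scale = hazard_scale,
              continuous_beta = continuous_beta)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (!is.numeric(cfg$n_stays) || cfg$n_stays <= 0) {
    stop("generator_config: n_stays must be positive", call. = FALSE)
  }
  if (abs(sum(cfg$bmi_group_probs) - 1) > 1e-9 ||
      any(cfg$bmi_group_probs < 0) || any(cfg$bmi_group_probs > 1)) {
    stop("generator_config: bmi_group_probs must be 6 probabilities ",
         "summing to 1", call. = FALSE)
  }
  if (cfg$los_mean_h <= 12) {
    stop("generator_config: los_mean_h must exceed 12 h", call. = FALSE)
  }
  if (abs(sum(cfg$site_probs) - 1) > 1e-9) {
    stop("generator_config: site_probs must sum to 1", call. = FALSE)
  }
  invisible(cfg)
}

#' Ground-truth hazard coefficients of the reference scenario
#'
#' BMI effects follow the reference scenario's monotone-decreasing ORs
#' (1.6, 1, 0.72, 0.65, 0.61, 0.53); the referent-cell per-window
#' hazard is 2%.
#'
#' @return Named numeric vector of log-odds.
#' @export
default_hazard_beta <- function() {
  c("(Intercept)" = stats::qlogis(0.02),
    "bmi_group=[0,18.5)" = log(1.6),
    "bmi_group=[25,30)" = log(0.72),
    "bmi_group=[30,35)" = log(0.65),
    "bmi_group=[35,40)" = log(0.61),
    "bmi_group=>=40" = log(0.53),
    "glucose_bin=[108,144)" = log(0.30),
    "glucose_bin=[144,180)" = log(0.26),
    "glucose_bin=>=180" = log(0.29),
    "insulin_bin=(0,2.5]" = log(2.18),
    "insulin_bin=(2.5,5]" = log(5.07),
    "insulin_bin=>5" = log(6.41),
    "lactate_bin=[2,5)" = log(1.6),
    "lactate_bin=>=5" = log(3.24),
    shock = log(1.48),
    pn = log(0.66), en = log(0.83), steroids = log(0.85),
    "dextrose_bin=(0,25)" = log(1.06),
    "dextrose_bin=>=25" = log(2.04),
    sofa_no_cardio = log(1.07),
    "database=hirid" = log(0.43),
    "database=mimic" = log(0.92),
    "database=eicu" = log(1.51))
}

#' @rdname default_hazard_beta
#' @export
default_mortality_beta <- function() {
  c("(Intercept)" = stats::qlogis(0.08),
    "bmi_group=[0,18.5)" = 0.5,
    "bmi_group=[25,30)" = -0.15,
    "bmi_group=[30,35)" = -0.30,
    "bmi_group=[35,40)" = -0.35,
    "bmi_group=>=40" = -0.25,
    any_hypo = log(2.5))
}

#' @rdname default_hazard_beta
#' @export
default_continuous_beta <- function() {
  c("(Intercept)" = stats::qlogis(0.02) + 110 * 0.012,
    glucose_mgdl = -0.012, lactate_mmoll = 0.25,
    insulin_max12_uh = 0.25, dextrose_d10_mlh = 0.02,
    shock = log(1.48), pn = log(0.66), en = log(0.83),
    steroids = log(0.85), sofa_no_cardio = log(1.07))
}

default_treatment_rules <- function() {
  list(insulin_prob_high = 0.80, insulin_prob_low = 0.15,
       insulin_glucose_threshold = 150,
       insulin_rate_meanlog = log(2), insulin_rate_sdlog = 0.7,
       bolus_prob = 0.15, hospital_insulin_range = c(0.45, 1.25),
       dextrose_prob = 0.05, dextrose_rate_range = c(10, 60),
       dextrose_conc = c(5, 10, 20), dextrose_conc_probs = c(0.3, 0.5, 0.2),
       pn_prob = 0.08, en_prob = 0.35, steroid_prob = 0.12,
       shock_prob = 0.25)
}

## BMI sampled uniformly within its group bin.
BMI_BIN_EDGES <- c(15, 18.5, 25, 30, 35, 40, 50)

#' Generate a synthetic ICU cohort
#'
#' Deterministic given `config$seed`. See [generator_config()] and the
#' methods vignette for the generative model.
#'
#' @param config A `generator_config`.
#' @return An `icu_cohort` with attribute `truth` (the event indicator
#'   and onset per stay as drawn by the generator).
#' @export
generate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_stays
  tr <- cfg$treatment_rules
  lv <- bmi_group_levels()

  ## -- statics ------------------------------------------------------
  site <- sample(cfg$site_labels, n, replace = TRUE, prob = cfg$site_probs)
  nh <- cfg$n_hospitals[site]
  hospital <- paste0(site, "_h",
                     sprintf("%02d", ceiling(stats::runif(n) * nh)))
  ## per-hospital insulin practice multiplier (underreporting emulation)
  hosp_ids <- sort(unique(hospital))
  hosp_mult <- stats::setNames(
    stats::runif(length(hosp_ids), tr$hospital_insulin_range[1L],
                 tr$hospital_insulin_range[2L]), hosp_ids)

  g <- sample.int(6L, n, replace = TRUE, prob = cfg$bmi_group_probs)
  bmi <- stats::runif(n, BMI_BIN_EDGES[g], BMI_BIN_EDGES[g + 1L])
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.58, 0.42))
  height <- stats::rnorm(n, ifelse(sex == "male", 1.76, 1.63), 0.07)
  weight <- bmi * height^2
  age <- stats::runif(n, 18, 95)
  adm <- sample(c("medical", "surgical", "other"), n, replace = TRUE,
                prob = c(0.63, 0.36, 0.01))
  diab <- stats::runif(n) < cfg$diabetes_prob[g]
  ## the diabetes flag is only recorded at the US-analog sites
  diab_rec <- ifelse(site %in% c("mimic", "eicu"), diab, NA)
  hba1c <- ifelse(diab, pmax(4.5, stats::rnorm(n, 7.5, 1.2)),
                  pmax(4.0, stats::rnorm(n, 5.5, 0.4)))
  hba1c_rec <- ifelse(site == "mimic" & stats::runif(n) < 0.20, hba1c,
                      NA_real_)
  los <- pmax(13, stats::rlnorm(n, log(cfg$los_mean_h) - 0.32, 0.8))

  ids <- sprintf("s%06d", seq_len(n))
  mu_glu <- cfg$mean_glucose_by_group[cbind(g, ifelse(diab, 2L, 1L))]
  shock_stay <- stats::runif(n) < tr$shock_prob

  ## -- per-stay time series -----------------------------------------
  phi <- cfg$glucose_ar1
  innov_sd <- cfg$glucose_sd * sqrt(1 - phi^2)
  ## glucose: renewal sampling, AR(1) latent level, floored above the
  ## hypoglycemia threshold (hypos are inserted by the hazard only)
  glu_t <- vector("list", n)
  glu_v <- vector("list", n)
  for (i in seq_len(n)) {
    L <- los[i]
    gaps <- pmin(20, pmax(0.5, stats::rexp(
      ceiling(L / cfg$measurement_gap_mean_h * 2.5) + 8,
      1 / cfg$measurement_gap_mean_h)))
    gt <- stats::runif(1, 0, 0.5) + c(0, cumsum(gaps))
    gt <- gt[gt <= L]
    e <- stats::rnorm(length(gt), 0, innov_sd)
    e[1L] <- stats::rnorm(1, 0, cfg$glucose_sd)
    glu_t[[i]] <- gt
    glu_v[[i]] <- pmax(71, mu_glu[i] +
                         as.numeric(stats::filter(e, phi, "recursive")))
  }
  k_glu <- lengths(glu_t)

  ## MAP every 2 h (shock stays run lower), lactate every 8 h, daily
  ## labs for the SOFA components -- all fully vectorized
  reg_times <- function(start, by) {
    k <- pmax(1L, floor((los - start) / by) + 1L)
    list(stay = rep(seq_len(n), k),
         t = rep(start, k) + by * (sequence(k) - 1L), k = k)
  }
  mp <- reg_times(rep(0.25, n), 2)
  map_v <- pmax(35, stats::rnorm(length(mp$t),
                                 ifelse(shock_stay[mp$stay], 64, 78), 9))
  lc <- reg_times(stats::runif(n, 0, 2), 8)
  lac_ml <- log(1.2) + 0.6 * shock_stay + stats::rnorm(n, 0, 0.35)
  lac_v <- stats::rlnorm(length(lc$t), lac_ml[lc$stay], 0.30)
  lb <- reg_times(rep(0.3, n), 24)
  nd <- length(lb$t)
  lab_v <- c(stats::rlnorm(nd, log(0.7), 0.8),
             pmax(5, stats::rnorm(nd, 220, 80)),
             stats::rlnorm(nd, log(0.9), 0.5),
             pmin(600, pmax(40, stats::rnorm(nd, 330, 120))),
             sample(c(15, 13, 10, 7, 3), nd, replace = TRUE,
                    prob = c(0.70, 0.12, 0.08, 0.06, 0.04)))
  lab_names <- c("bilirubin_mgdl", "platelets_e3ul", "creatinine_mgdl",
                 "pao2fio2", "gcs")
  measurements <- data.table::data.table(
    stay_id = c(rep(ids, k_glu), ids[mp$stay], ids[lc$stay],
                rep(ids[lb$stay], 5L)),
    variable = c(rep("glucose_mgdl", sum(k_glu)),
                 rep("map_mmhg", length(mp$t)),
                 rep("lactate_mmoll", length(lc$t)),
                 rep(lab_names, each = nd)),
    time_h = c(unlist(glu_t, use.names = FALSE), mp$t, lc$t,
               rep(lb$t, 5L)),
    value = c(unlist(glu_v, use.names = FALSE), map_v, lac_v, lab_v))

  ## -- treatments ---------------------------------------------------
  ins_p <- ifelse(mu_glu > tr$insulin_glucose_threshold,
                  tr$insulin_prob_high, tr$insulin_prob_low) *
    hosp_mult[hospital]
  on_ins <- stats::runif(n) < pmin(1, ins_p)
  rates_list <- list()
  idx <- which(on_ins)
  if (length(idx)) {
    s0 <- floor(stats::runif(length(idx), 0, pmax(1, los[idx] / 2)))
    e0 <- pmin(floor(los[idx]), s0 + round(stats::runif(length(idx), 6, 48)))
    ok <- e0 > s0
    rates_list$insulin <- data.table::data.table(
      stay_id = ids[idx][ok], drug = "insulin", start_h = s0[ok],
      end_h = e0[ok],
      rate = stats::rlnorm(sum(ok), tr$insulin_rate_meanlog,
                           tr$insulin_rate_sdlog),
      concentration_pct = NA_real_, bolus = FALSE)
    bol <- which(ok)[stats::runif(sum(ok)) < tr$bolus_prob]
    if (length(bol)) {
      bt <- s0[bol] + 0.5 + floor(stats::runif(length(bol)) *
                                  pmax(1, e0[bol] - s0[bol] - 1))
      rates_list$bolus <- data.table::data.table(
        stay_id = ids[idx][bol], drug = "insulin", start_h = bt,
        end_h = bt, rate = stats::runif(length(bol), 2, 8),
        concentration_pct = NA_real_, bolus = TRUE)
    }
  }
  idx <- which(stats::runif(n) < tr$dextrose_prob)
  if (length(idx)) {
    s0 <- floor(stats::runif(length(idx), 0, pmax(1, los[idx] - 8)))
    e0 <- pmin(floor(los[idx]), s0 + round(stats::runif(length(idx), 4, 36)))
    ok <- e0 > s0
    rates_list$dextrose <- data.table::data.table(
      stay_id = ids[idx][ok], drug = "dextrose", start_h = s0[ok],
      end_h = e0[ok],
      rate = stats::runif(sum(ok), tr$dextrose_rate_range[1L],
                          tr$dextrose_rate_range[2L]),
      concentration_pct = sample(tr$dextrose_conc, sum(ok), replace = TRUE,
                                 prob = tr$dextrose_conc_probs),
      bolus = FALSE)
  }
  idx <- which(shock_stay)
  if (length(idx)) {
    rates_list$vaso <- data.table::data.table(
      stay_id = ids[idx], drug = "vasopressor", start_h = 0,
      end_h = pmin(los[idx], round(stats::runif(length(idx), 6, 48))),
      rate = stats::runif(length(idx), 0.05, 0.5),
      concentration_pct = NA_real_, bolus = FALSE)
    rates_list$vaso <- rates_list$vaso[end_h > start_h]
  }
  rates <- data.table::rbindlist(rates_list)
  if (!nrow(rates)) rates <- empty_rates()

  flag_block <- function(expo, prob) {
    idx <- which(stats::runif(n) < prob)
    if (!length(idx)) return(NULL)
    s0 <- floor(stats::runif(length(idx), 0, pmax(0.5, los[idx] / 3)))
    e0 <- pmin(los[idx], s0 + stats::runif(length(idx), 6, 72))
    keep <- e0 > s0
    data.table::data.table(stay_id = ids[idx][keep], exposure = expo,
                           start_h = s0[keep], end_h = e0[keep])
  }
  flags <- data.table::rbindlist(list(
    flag_block("parenteral_nutrition", tr$pn_prob),
    flag_block("enteral_nutrition", tr$en_prob),
    flag_block("corticosteroids", tr$steroid_prob)))
  if (!nrow(flags)) flags <- empty_flags()

  stays <- data.table::data.table(
    stay_id = ids, database = site, hospital_id = hospital,
    age_years = age, sex = sex, height_m = height, weight_kg = weight,
    bmi = bmi, admission_type = adm, diabetes = diab_rec,
    hba1c_pct = hba1c_rec, los_icu_h = los, hospital_mortality = FALSE)

  pre <- icu_cohort(stays, measurements, rates, flags)

  ## -- hypoglycemia events from the logistic hazard -----------------
  W <- window_feature_table(pre, window_h = 6)
  W[, glucose_bin := bin_glucose(pmax(glucose_mgdl, 70))]
  W[, insulin_bin := bin_insulin(insulin_max12_uh)]
  W[, lactate_bin := bin_lactate(lactate_mmoll)]
  W[, dextrose_bin := bin_dextrose(dextrose_d10_mlh)]
  lp <- hazard_linear_predictor(W, cfg)
  W[, p := stats::plogis(lp)]
  W[, u := stats::runif(.N)]
  ev <- W[u < p, list(feature_time_h = feature_time_h[1L]), by = stay_id]
  ev[stays, los := i.los_icu_h, on = "stay_id"]
  ev[, onset := feature_time_h +
       stats::runif(.N, 0, pmin(6, los - feature_time_h))]
  ev[, hypo_value := stats::runif(.N, 40, 70)]

  if (nrow(ev)) {
    ins_rows <- data.table::data.table(
      stay_id = ev$stay_id, variable = "glucose_mgdl",
      time_h = ev$onset, value = ev$hypo_value)
    measurements <- data.table::rbindlist(list(measurements, ins_rows))
    ## avoid (stay, variable, time) duplicates with the continuous draw
    measurements <- unique(measurements,
                           by = c("stay_id", "variable", "time_h"))
  }

  ## -- mortality ----------------------------------------------------
  mb <- cfg$mortality_beta
  any_hypo <- ids %in% ev$stay_id
  bmi_key <- paste0("bmi_group=", lv[g])
  bmi_eff <- ifelse(bmi_key %in% names(mb), mb[bmi_key], 0)
  lp_m <- mb[["(Intercept)"]] + bmi_eff +
    ifelse(any_hypo, mb[["any_hypo"]], 0)
  stays[, hospital_mortality := stats::runif(n) < stats::plogis(lp_m)]

  out <- icu_cohort(stays, measurements, rates, flags)
  attr(out, "truth") <- ev[, list(stay_id, event_window_h = feature_time_h,
                                  onset_h = onset)]
  out
}

## Linear predictor of the event hazard for the generated windows.
hazard_linear_predictor <- function(W, cfg) {
  if (cfg$hazard_scale == "binned") {
    beta <- cfg$hazard_beta
    bval <- function(key) ifelse(is.na(beta[key]), 0, beta[key])
    lp <- rep(beta[["(Intercept)"]], nrow(W))
    lp <- lp + bval(paste0("bmi_group=", as.character(W$bmi_group)))
    lp <- lp + bval(paste0("glucose_bin=", as.character(W$glucose_bin)))
    lp <- lp + bval(paste0("insulin_bin=", as.character(W$insulin_bin)))
    lp <- lp + bval(paste0("lactate_bin=", as.character(W$lactate_bin)))
    lp <- lp + bval(paste0("dextrose_bin=", as.character(W$dextrose_bin)))
    lp <- lp + bval(paste0("database=", as.character(W$database)))
    lp <- lp + W$shock * bval("shock") + W$pn * bval("pn") +
      W$en * bval("en") + W$steroids * bval("steroids") +
      W$sofa_no_cardio * bval("sofa_no_cardio")
    unname(lp)
  } else {
    cb <- cfg$continuous_beta
    cval <- function(key) if (key %in% names(cb)) cb[[key]] else 0
    lp <- rep(cb[["(Intercept)"]], nrow(W))
    for (v in c("glucose_mgdl", "lactate_mmoll", "insulin_max12_uh",
                "dextrose_d10_mlh", "sofa_no_cardio")) {
      lp <- lp + as.numeric(W[[v]]) * cval(v)
    }
    lp <- lp + W$shock * cval("shock") + W$pn * cval("pn") +
      W$en * cval("en") + W$steroids * cval("steroids")
    beta <- cfg$hazard_beta
    bmi_eff <- beta[paste0("bmi_group=", as.character(W$bmi_group))]
    lp + ifelse(is.na(bmi_eff), 0, bmi_eff)
  }
}

#' Ground-truth odds ratios of a generator configuration
#'
#' ORs are `exp(hazard_beta)`, keyed identically to the `or_table` of
#' [fit_pooled_logistic()] so recovery tests can join on `key`.
#'
#' @param config A `generator_config`.
#' @return data.table with `term`, `level`, `key`, `log_or`, `or_true`.
#' @export
truth_table <- function(config = generator_config()) {
  beta <- config$hazard_beta
  beta <- beta[names(beta) != "(Intercept)"]
  keys <- names(beta)
  term <- sub("=.*$", "", keys)
  level <- ifelse(grepl("=", keys), sub("^[^=]*=", "", keys), "")
  out <- data.table::data.table(term = term, level = level,
                                log_or = unname(beta),
                                or_true = exp(unname(beta)))
  out[, key := keys]
  data.table::setcolorder(out, c("term", "level", "key"))
  out[]
}
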