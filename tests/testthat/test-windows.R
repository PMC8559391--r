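test_that("build_windows places H and censors per the stated iteration", {
  ## discharge 20, onset 14 -> records at 6 (H=0) and 12 (H=1)
  w <- build_windows(list(stay_id = "x", los_icu_h = 20), 14)
  expect_equal(w$feature_time_h, c(6, 12))
  expect_equal(w$H, c(0L, 1L))
  ## discharge 15, no hypo -> 6 and 12, both 0 (partial terminal window)
  w2 <- build_windows(list(stay_id = "x", los_icu_h = 15), NA_real_)
  expect_equal(w2$feature_time_h, c(6, 12))
  expect_equal(w2$H, c(0L, 0L))
  ## onset before the first feature time -> no records
  expect_equal(nrow(build_windows(list(stay_id = "x", los_icu_h = 30), 3)), 0L)
  expect_equal(nrow(build_windows(list(stay_id = "x", los_icu_h = 30), 6)), 0L)
  ## onset exactly at a feature time counts in the preceding window
  w3 <- build_windows(list(stay_id = "x", los_icu_h = 40), 12)
  expect_equal(w3$feature_time_h, 6)
  expect_equal(w3$H, 1L)
  ## accepts an episode_set as the onset carrier
  eps <- build_episodes(data.frame(time_h = c(2, 14), value = c(100, 60)),
                        discharge_h = 20)
  w4 <- build_windows(list(stay_id = "x", los_icu_h = 20), eps)
  expect_equal(w4$H, c(0L, 1L))
})

test_that("build_windows matches the enumerator oracle on random stays", {
  set.seed(99)
  for (i in 1:300) {
    discharge <- runif(1, 1, 200)
    onset <- if (runif(1) < 0.5) NA_real_ else runif(1, 0, discharge)
    got <- build_windows(list(stay_id = "x", los_icu_h = discharge), onset)
    want <- oracle_windows(discharge, onset)
    expect_equal(got$feature_time_h, want$feature_time_h)
    expect_equal(got$H, want$H)
    expect_lte(sum(got$H), 1L)
    if (!is.na(onset)) expect_true(all(got$feature_time_h < onset))
  }
})

test_that("bin_covariates partitions every covariate", {
  v <- data.frame(glucose_mgdl = 108, insulin_max12_uh = 2.5,
                  lactate_mmoll = 2, dextrose_d10_mlh = 25)
  b <- bin_covariates(v)
  expect_equal(as.character(b$glucose_bin), "[108,144)")
  expect_equal(as.character(b$insulin_bin), "(0,2.5]")  # right-closed
  expect_equal(as.character(b$lactate_bin), "[2,5)")    # left-closed
  expect_equal(as.character(b$dextrose_bin), ">=25")
  ## referents
  b0 <- bin_covariates(data.frame(glucose_mgdl = 70, insulin_max12_uh = 0,
                                  lactate_mmoll = 0, dextrose_d10_mlh = 0))
  expect_equal(as.character(b0$glucose_bin), "[70,108)")
  expect_equal(as.character(b0$insulin_bin), "0")
  expect_equal(as.character(b0$dextrose_bin), "0")
  ## glucose below 70 warns and lands in the referent bin
  expect_warning(
    b_low <- bin_covariates(data.frame(glucose_mgdl = 60,
                                       insulin_max12_uh = 0,
                                       lactate_mmoll = 1,
                                       dextrose_d10_mlh = 0)),
    "referent")
  expect_equal(as.character(b_low$glucose_bin), "[70,108)")
  ## partition property over random values
  set.seed(5)
  x <- data.frame(glucose_mgdl = runif(200, 70, 400),
                  insulin_max12_uh = runif(200, 0, 12),
                  lactate_mmoll = runif(200, 0, 12),
                  dextrose_d10_mlh = runif(200, 0, 80))
  bb <- bin_covariates(x)
  expect_false(anyNA(bb$glucose_bin) || anyNA(bb$insulin_bin) ||
               anyNA(bb$lactate_bin) || anyNA(bb$dextrose_bin))
})

test_that("filter_hospitals excludes below-threshold hospitals strictly", {
  set.seed(11)
  mk_stays <- function(hosp, n, db = "eicu") data.frame(
    stay_id = paste0(hosp, "_", seq_len(n)), database = db,
    hospital_id = hosp, age_years = 50, sex = "male", height_m = 1.75,
    weight_kg = 80, bmi = NA, admission_type = "medical", diabetes = NA,
    hba1c_pct = NA, los_icu_h = 24, hospital_mortality = FALSE)
  stays <- rbind(mk_stays("h15", 20), mk_stays("h20", 20),
                 mk_stays("h25", 20), mk_stays("solo", 20, db = "aumc"))
  give_insulin <- function(ids) data.frame(
    stay_id = ids, drug = "insulin", start_h = 0, end_h = 4, rate = 2,
    concentration_pct = NA_real_, bolus = FALSE)
  rates <- rbind(give_insulin(paste0("h15_", 1:3)),    # 15%
                 give_insulin(paste0("h20_", 1:4)),    # exactly 20%
                 give_insulin(paste0("h25_", 1:5)),    # 25%
                 give_insulin(paste0("solo_", 1:2)))   # 10%, single-hosp site
  co <- icu_cohort(stays, rates = rates)
  filt <- filter_hospitals(co, 0.20)
  kept <- unique(filt$stays$hospital_id)
  expect_false("h15" %in% kept)        # 15% < 20% -> excluded
  expect_true("h20" %in% kept)         # exactly 20% kept (strict <)
  expect_true("h25" %in% kept)
  expect_true("solo" %in% kept)        # single-hospital site not filtered
})

test_that("assemble_design conserves per-stay window counts", {
  co <- generate_cohort(small_config(n_stays = 120, seed = 8))
  d <- assemble_design(co)
  glyc <- glycemia_table(co)
  expected <- sum(vapply(seq_len(nrow(co$stays)), function(i) {
    nrow(build_windows(co$stays[i], glyc$first_onset_h[i]))
  }, numeric(1)))
  expect_equal(nrow(d), expected)
  expect_lte(max(d[, sum(H), by = stay_id]$V1), 1L)
  ## referents recorded for every categorical term
  expect_equal(attr(d, "referents")[["bmi_group"]], "[18.5,25)")
  expect_equal(attr(d, "referents")[["database"]],
               sort(unique(co$stays$database))[1])
})

test_that("vectorized window covariates agree with covariate_vector", {
  co <- generate_cohort(small_config(n_stays = 25, seed = 13))
  W <- glycohazard:::window_feature_table(co)
  med <- cohort_medians(co)
  idx <- sample(nrow(W), 40)
  for (i in idx) {
    v <- covariate_vector(co, W$stay_id[i], W$feature_time_h[i],
                          medians = med)
    expect_equal(W$glucose_mgdl[i], v$glucose_mgdl)
    expect_equal(W$lactate_mmoll[i], v$lactate_mmoll)
    expect_equal(W$shock[i], v$shock)
    expect_equal(W$insulin_max12_uh[i], v$insulin_max12_uh)
    expect_equal(W$dextrose_d10_mlh[i], v$dextrose_d10_mlh)
    expect_equal(W$pn[i], v$pn)
    expect_equal(W$en[i], v$en)
    expect_equal(W$steroids[i], v$steroids)
    expect_equal(W$sofa_no_cardio[i], v$sofa_no_cardio)
  }
})

test_that("diabetes adjustment restricts to flag-carrying databases", {
  co <- generate_cohort(small_config(n_stays = 400, seed = 21))
  d <- assemble_design(co, adjust_diabetes = TRUE)
  expect_true(all(levels(d$database) %in% c("eicu", "mimic")))
  expect_true(all(!is.na(d$diabetes)))
  d0 <- assemble_design(co)
  expect_false("diabetes" %in% names(d0))
  ## no carrier -> error
  co2 <- co
  co2$stays[, diabetes := NA]
  expect_error(assemble_design(co2, adjust_diabetes = TRUE), "diabetes")
})
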