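series <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(time_h = m[, 1], value = m[, 2])
}

test_that("value_at bounds carry-forward by the class horizon", {
  s <- series(0, 1.5)
  ## infrequent (daily lab): carried up to 48 h
  expect_equal(value_at(s, 47, "infrequent", 9)$value, 1.5)
  expect_equal(value_at(s, 47, "infrequent", 9)$provenance, "carried")
  expect_equal(value_at(s, 49, "infrequent", 9)$provenance, "median")
  ## frequent: carried up to 24 h only
  expect_equal(value_at(s, 25, "frequent", 9)$value, 9)
  expect_equal(value_at(s, 24, "frequent", 9)$value, 1.5)
  ## exactly at an observation: observed
  expect_equal(value_at(s, 0, "frequent", 9)$provenance, "observed")
  expect_error(value_at(s, 49, "infrequent", NA_real_), "median")
})

test_that("value_at provenance transitions observed -> carried -> median", {
  s <- series(2, 100)
  prov <- vapply(c(2, 10, 20, 26.5), function(t)
    value_at(s, t, "frequent", 50)$provenance, character(1))
  expect_equal(prov, c("observed", "carried", "carried", "median"))
  ## step function: idempotent between observations
  s2 <- series(0, 80, 6, 120)
  expect_equal(value_at(s2, 3, "frequent", 50)$value,
               value_at(s2, 5.9, "frequent", 50)$value)
})

test_that("shock_flag uses MAP < 60 or any vasopressor", {
  no_vaso <- data.frame(start_h = numeric(0), end_h = numeric(0))
  vaso <- data.frame(start_h = 0, end_h = 12)
  expect_true(shock_flag(series(1, 55), no_vaso, 2))
  expect_true(shock_flag(series(1, 65), vaso, 2))
  expect_false(shock_flag(series(1, 72), no_vaso, 2))
  expect_false(shock_flag(series(1, 72), vaso, 13))  # pressor ended
})

test_that("max_insulin_12h takes the max hourly bin dose", {
  iv <- data.frame(start_h = c(0, 5), end_h = c(5, 8), rate = c(2, 4),
                   bolus = FALSE)
  expect_equal(max_insulin_12h(iv, 10), 4)
  expect_equal(max_insulin_12h(iv, 17), 4)   # only [5,8) is inside (5, 17]
  expect_equal(max_insulin_12h(iv, 21), 0)   # all insulin before (9, 21]
  expect_equal(max_insulin_12h(data.frame(start_h = numeric(0),
                                          end_h = numeric(0),
                                          rate = numeric(0),
                                          bolus = logical(0)), 10), 0)
  ## background 1 u/h + 3 U bolus in hour (8,9] -> 4 in that bin
  iv2 <- data.frame(start_h = c(0, 9), end_h = c(24, 9), rate = c(1, 3),
                    bolus = c(FALSE, TRUE))
  expect_equal(max_insulin_12h(iv2, 10), 4)
  ## monotone under adding an infusion
  iv3 <- rbind(iv, data.frame(start_h = 6, end_h = 7, rate = 1,
                              bolus = FALSE))
  expect_gte(max_insulin_12h(iv3, 10), max_insulin_12h(iv, 10))
})

test_that("dextrose_d10_rate normalizes to D10 and excludes D5", {
  d10 <- data.frame(start_h = 0, end_h = 24, rate = 30,
                    concentration_pct = 10)
  d20 <- data.frame(start_h = 0, end_h = 24, rate = 20,
                    concentration_pct = 20)
  d5 <- data.frame(start_h = 0, end_h = 24, rate = 100,
                   concentration_pct = 5)
  expect_equal(dextrose_d10_rate(d10, 6), 30)
  expect_equal(dextrose_d10_rate(d20, 6), 40)
  expect_equal(dextrose_d10_rate(d5, 6), 0)
  expect_equal(dextrose_d10_rate(rbind(d10, d20, d5), 6), 70)  # linearity
  expect_error(dextrose_d10_rate(
    data.frame(start_h = 0, end_h = 2, rate = 5, concentration_pct = 7), 1),
    "concentration")
})

test_that("SOFA components follow the standard thresholds", {
  meas <- data.frame(
    variable = c("pao2fio2", "platelets_e3ul", "bilirubin_mgdl",
                 "map_mmhg", "gcs", "creatinine_mgdl"),
    time_h = 1, value = c(450, 300, 0.5, 80, 15, 0.8))
  no_vaso <- data.frame(start_h = numeric(0), end_h = numeric(0))
  sc <- sofa_components(meas, no_vaso, 2, list())
  expect_equal(sc$total, 0)
  ## platelets 90 -> coagulation 2
  meas2 <- meas; meas2$value[meas2$variable == "platelets_e3ul"] <- 90
  expect_equal(sofa_components(meas2, no_vaso, 2, list())$coagulation, 2L)
  ## MAP 55 without vasopressors -> cardiovascular 1
  meas3 <- meas; meas3$value[meas3$variable == "map_mmhg"] <- 55
  sc3 <- sofa_components(meas3, no_vaso, 2, list())
  expect_equal(sc3$cardiovascular, 1L)
  ## any vasopressor -> cardiovascular 2
  sc4 <- sofa_components(meas, data.frame(start_h = 0, end_h = 6), 2, list())
  expect_equal(sc4$cardiovascular, 2L)
  expect_equal(sc4$no_cardio, sc4$total - sc4$cardiovascular)
  ## monotone in severity
  sev <- sapply(c(450, 350, 250, 150, 50), function(pf) {
    m <- meas; m$value[m$variable == "pao2fio2"] <- pf
    sofa_components(m, no_vaso, 2, list())$respiratory
  })
  expect_equal(sev, 0:4)
})

test_that("covariate_vector assembles the fixture stay correctly", {
  co <- fixture_cohort()
  v <- covariate_vector(co, "a", 6)
  expect_equal(v$glucose_mgdl, 95)           # last obs at 4 h
  expect_equal(v$lactate_mmoll, 1.5)
  expect_false(v$shock)                      # MAP 72, no pressor
  expect_equal(v$insulin_max12_uh, 2)        # infusion 2 u/h on [0,5)
  expect_equal(v$dextrose_d10_mlh, 0)
  expect_true(v$en); expect_false(v$pn); expect_false(v$steroids)
  expect_equal(v$sofa_no_cardio + v$sofa_cardio, v$sofa_total)
  ## bolus hour: 3 U at t = 9 within (t-12, t]
  v10 <- covariate_vector(co, "a", 10)
  expect_equal(v10$insulin_max12_uh, 3)
  ## stay with vasopressor -> shock
  expect_true(covariate_vector(co, "b", 6)$shock)
  ## stay with no treatments
  vc <- covariate_vector(co, "c", 6)
  expect_equal(vc$insulin_max12_uh, 0)
  expect_false(vc$pn || vc$en)
  expect_true(vc$steroids)
})

test_that("missingness_report counts stays without usable observations", {
  co <- fixture_cohort()
  rep <- missingness_report(co, t = 24, variables = c("glucose_mgdl",
                                                      "lactate_mmoll"))
  ## every stay has glucose near 24 h
  expect_true(all(rep[variable == "glucose_mgdl", missing_frac] == 0))
  ## only stay a has lactate
  lac <- rep[variable == "lactate_mmoll"]
  expect_equal(sum(lac$missing_frac * lac$n), 2)  # stays b and c missing
})
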