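## Independent oracles and in-code fixtures shared across test files.

## Episode oracle built from a different construction than the package's
## sequential scan: each hypoglycemic measurement defines a candidate
## interval [t, min(t + 6, first non-hypo time after t)]; episodes are
## the unions of candidate chains, merging a candidate into the current
## episode iff its start lies strictly inside it. Ends are clipped at
## discharge. Ties (a hypo exactly at a provisional end) start a new
## episode, matching the stated tie-break.
oracle_episodes <- function(t, v, discharge = Inf, threshold = 70) {
  hypo <- v <= threshold
  ht <- t[hypo]
  if (!length(ht)) {
    return(data.frame(start_h = numeric(0), end_h = numeric(0),
                      n_hypo_measurements = integer(0)))
  }
  cand_end <- vapply(ht, function(h) {
    later_non <- t[!hypo & t > h]
    min(h + 6, if (length(later_non)) min(later_non) else Inf)
  }, numeric(1))
  starts <- ends <- numeric(0)
  cur_s <- ht[1L]; cur_e <- cand_end[1L]
  for (i in seq_along(ht)[-1L]) {
    if (ht[i] < cur_e) {
      cur_e <- max(cur_e, cand_end[i])
    } else {
      starts <- c(starts, cur_s); ends <- c(ends, cur_e)
      cur_s <- ht[i]; cur_e <- cand_end[i]
    }
  }
  starts <- c(starts, cur_s); ends <- c(ends, cur_e)
  ends <- pmin(ends, discharge)
  n_in <- vapply(seq_along(starts), function(k) {
    sum(ht >= starts[k] & ht <= ends[k])
  }, integer(1))
  data.frame(start_h = starts, end_h = ends, n_hypo_measurements = n_in)
}

## Window enumerator oracle: explicit iteration over successive 6-h
## windows, stopping at the event window, the onset or discharge.
oracle_windows <- function(discharge, onset = NA_real_, window_h = 6) {
  ft <- window_h
  fts <- integer(0); H <- integer(0)
  lim <- if (is.na(onset)) discharge else min(discharge, onset)
  repeat {
    if (ft >= lim) break
    h <- as.integer(!is.na(onset) && onset > ft & onset <= ft + window_h)
    fts <- c(fts, ft); H <- c(H, h)
    if (h == 1L) break
    ft <- ft + window_h
  }
  data.frame(feature_time_h = fts, H = H)
}

## Random sparse glucose series for property tests.
random_series <- function(n_max = 30, p_hypo = 0.3) {
  n <- sample.int(n_max, 1L)
  gaps <- runif(n, 0.5, 12)
  t <- cumsum(gaps)
  v <- ifelse(runif(n) < p_hypo, runif(n, 40, 70), runif(n, 75, 250))
  data.frame(time_h = t, value = v)
}

## Tiny deterministic three-stay cohort used across module tests.
fixture_cohort <- function() {
  stays <- data.frame(
    stay_id = c("a", "b", "c"),
    database = c("siteA", "siteA", "siteB"),
    hospital_id = c("h1", "h1", "h2"),
    age_years = c(60, 45, 72),
    sex = c("male", "female", "male"),
    height_m = c(1.8, 1.6, NA),
    weight_kg = c(81, 64, NA),
    bmi = c(NA, NA, 33.1),
    admission_type = c("medical", "surgical", "medical"),
    diabetes = c(TRUE, FALSE, NA),
    hba1c_pct = c(7.6, NA, 6.2),
    los_icu_h = c(48, 30, 72),
    hospital_mortality = c(FALSE, TRUE, FALSE))
  measurements <- data.frame(
    stay_id = c(rep("a", 6), rep("b", 4), rep("c", 3),
                "a", "a", "a", "a", "a", "a"),
    variable = c(rep("glucose_mgdl", 6), rep("glucose_mgdl", 4),
                 rep("glucose_mgdl", 3),
                 "lactate_mmoll", "map_mmhg", "bilirubin_mgdl",
                 "platelets_e3ul", "creatinine_mgdl", "pao2fio2"),
    time_h = c(0, 4, 10, 14, 20, 30,   1, 8, 15, 22,   0, 24, 48,
               2, 5, 1, 1, 1, 1),
    value = c(120, 95, 160, 68, 90, 110,   140, 150, 135, 180,
              200, 210, 190,
              1.5, 72, 0.8, 250, 1.0, 380))
  rates <- data.frame(
    stay_id = c("a", "a", "b"),
    drug = c("insulin", "insulin", "vasopressor"),
    start_h = c(0, 9, 0), end_h = c(5, 9, 12),
    rate = c(2, 3, 0.2),
    concentration_pct = NA_real_,
    bolus = c(FALSE, TRUE, FALSE))
  flags <- data.frame(
    stay_id = c("a", "c"),
    exposure = c("enteral_nutrition", "corticosteroids"),
    start_h = c(2, 0), end_h = c(20, 30))
  icu_cohort(stays, measurements, rates, flags)
}

## Small, fast generator scenario for tests that need a full cohort.
small_config <- function(n_stays = 300, seed = 42, ...) {
  generator_config(n_stays = n_stays, seed = seed, ...)
}
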