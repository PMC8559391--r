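## Build a minimal design_table by hand for closed-form checks.
manual_design <- function(df) {
  dt <- data.table::as.data.table(df)
  referents <- c(bmi_group = "[18.5,25)", glucose_bin = "[70,108)",
                 insulin_bin = "0", lactate_bin = "[0,2)",
                 dextrose_bin = "0",
                 database = if ("database" %in% names(dt))
                   sort(unique(as.character(dt$database)))[1] else "siteA")
  structure(dt, class = c("design_table", class(dt)),
            referents = referents, window_h = 6)
}

test_that("saturated 2x2 logistic fit equals the cross-product OR", {
  ## exposed: 10 events / 100; unexposed: 20 events / 100
  d <- manual_design(data.frame(
    H = c(rep(1, 10), rep(0, 90), rep(1, 20), rep(0, 80)),
    shock = rep(c(TRUE, FALSE), c(100, 100))))
  fit <- fit_pooled_logistic(d)
  or_hat <- fit$or_table[term == "shock", or]
  expect_equal(or_hat, (10 * 80) / (90 * 20), tolerance = 1e-6)
  ## Wald CI brackets the OR and uses z = 1.959964
  row <- fit$or_table[term == "shock"]
  expect_lt(row$lo, row$or); expect_gt(row$hi, row$or)
  expect_equal(row$hi / row$or, exp(1.959964 * row$se), tolerance = 1e-10)
})

test_that("null predictor yields a CI containing 1", {
  set.seed(31)
  n <- 4000
  d <- manual_design(data.frame(H = rbinom(n, 1, 0.1),
                                shock = runif(n) < 0.5))
  row <- fit_pooled_logistic(d)$or_table[term == "shock"]
  expect_lt(row$lo, 1); expect_gt(row$hi, 1)
})

test_that("empty covariate levels are dropped with a warning", {
  set.seed(32)
  n <- 500
  d <- manual_design(data.frame(
    H = rbinom(n, 1, 0.2),
    bmi_group = factor(sample(c("[18.5,25)", "[25,30)"), n, replace = TRUE),
                       levels = bmi_group_levels())))
  expect_warning(fit <- fit_pooled_logistic(d, compute_chi2 = FALSE),
                 "empty level")
  expect_equal(fit$or_table$level, "[25,30)")
})

test_that("separation and singular designs raise errors", {
  d <- manual_design(data.frame(H = rep(c(1, 0), each = 50),
                                shock = rep(c(TRUE, FALSE), each = 50)))
  expect_error(fit_pooled_logistic(d), "separation|converge")
  set.seed(33)
  d2 <- manual_design(data.frame(H = rbinom(100, 1, 0.3),
                                 shock = rep(c(TRUE, FALSE), 50),
                                 pn = rep(c(TRUE, FALSE), 50)))
  expect_error(fit_pooled_logistic(d2), "singular|aliased")
})

test_that("gvif matches the two-predictor closed form", {
  set.seed(34)
  n <- 2000
  x1 <- scale(rnorm(n))[, 1]
  e <- scale(residuals(lm(rnorm(n) ~ x1)))[, 1]
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * e        # sample correlation exactly 0.9
  expect_equal(cor(x1, x2), 0.9, tolerance = 1e-12)
  d <- data.frame(H = rbinom(n, 1, 0.2), sofa_no_cardio = x1, shock = x2)
  dm <- glycohazard:::design_matrix(manual_design(d))
  g <- glycohazard:::gvif_from_matrix(dm$X[, -1], dm$term_map)
  expect_equal(g[term == "shock", gvif], 1 / (1 - 0.81), tolerance = 1e-6)
  ## orthogonal predictors -> GVIF 1
  d2 <- data.frame(H = rbinom(n, 1, 0.2),
                   sofa_no_cardio = rep(c(1, 0), n / 2),
                   shock = rep(c(TRUE, TRUE, FALSE, FALSE), n / 4))
  dm2 <- glycohazard:::design_matrix(manual_design(d2))
  g2 <- glycohazard:::gvif_from_matrix(dm2$X[, -1], dm2$term_map)
  expect_equal(g2$gvif, c(1, 1), tolerance = 1e-6)
  expect_equal(g2$gvif_adj, sqrt(g2$gvif), tolerance = 1e-12)
})

test_that("categorical_chi2 is a likelihood-ratio test", {
  set.seed(35)
  n <- 3000
  g <- factor(sample(bmi_group_levels()[1:3], n, replace = TRUE),
              levels = bmi_group_levels())
  p <- ifelse(g == "[0,18.5)", 0.25, 0.10)
  d <- manual_design(data.frame(H = rbinom(n, 1, p), bmi_group = g))
  out <- suppressWarnings(categorical_chi2(d, "bmi_group"))
  expect_equal(out$df, 2L)
  expect_lt(out$p, 0.001)
  ## cross-check against glm anova on the same data
  ref <- suppressWarnings(
    anova(glm(d$H ~ droplevels(d$bmi_group), family = binomial()),
          test = "LRT"))
  expect_equal(out$statistic, ref$Deviance[2], tolerance = 1e-8)
  expect_error(suppressWarnings(categorical_chi2(d, "nope")),
               "unknown term")
})

test_that("cluster-robust SEs keep the point estimates and stay sane", {
  co <- generate_cohort(small_config(n_stays = 600, seed = 61))
  d <- assemble_design(co)
  f0 <- suppressWarnings(fit_pooled_logistic(d, compute_chi2 = FALSE))
  f1 <- suppressWarnings(fit_pooled_logistic(d, compute_chi2 = FALSE,
                                             cluster_se = TRUE))
  expect_equal(f1$or_table$or, f0$or_table$or)          # same MLE
  expect_true(all(is.finite(f1$or_table$se) & f1$or_table$se > 0))
  ## windows are conditionally independent here, so robust and
  ## model-based SEs should be of the same order for well-estimated
  ## levels (quasi-separated levels have degenerate sandwich SEs)
  ok <- f0$or_table$se < 10
  ratio <- f1$or_table$se[ok] / f0$or_table$se[ok]
  expect_true(all(ratio > 0.5 & ratio < 2))
  expect_error(fit_pooled_logistic(d[, !"stay_id"], cluster_se = TRUE),
               "stay_id")
})

test_that("bootstrap_mean_ci is deterministic, covering and equivariant", {
  ## constant data -> zero-width interval
  b <- bootstrap_mean_ci(rep(3.5, 20), seed = 1)
  expect_equal(b$lower, 3.5); expect_equal(b$upper, 3.5)
  ## determinism given seed, default B = 500
  x <- rnorm(100)
  expect_identical(bootstrap_mean_ci(x, seed = 9),
                   bootstrap_mean_ci(x, seed = 9))
  expect_equal(formals(bootstrap_mean_ci)$B, 500)
  ## affine equivariance (positive slope)
  b1 <- bootstrap_mean_ci(x, seed = 4)
  b2 <- bootstrap_mean_ci(2 * x + 10, seed = 4)
  expect_equal(b2$lower, 2 * b1$lower + 10, tolerance = 1e-12)
  expect_equal(b2$upper, 2 * b1$upper + 10, tolerance = 1e-12)
  expect_error(bootstrap_mean_ci(numeric(0)), "no finite values")
  ## caller's RNG stream is not disturbed
  set.seed(77); r1 <- runif(1)
  set.seed(77); invisible(bootstrap_mean_ci(x, seed = 5)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("compare_bmi_halves dispatches chi2 vs Mann-Whitney", {
  groups <- rep(c("[18.5,25)", "[25,30)"), each = 100)
  ## 2x2: 30/70 vs 10/90, Pearson without continuity correction
  flags <- c(rep(TRUE, 30), rep(FALSE, 70), rep(TRUE, 10), rep(FALSE, 90))
  out <- compare_bmi_halves(flags, groups)
  expect_equal(out$test, "chi2")
  expect_equal(out$statistic,
               200 * (30 * 90 - 70 * 10)^2 / (100 * 100 * 40 * 160),
               tolerance = 1e-10)
  ## continuous -> Mann-Whitney
  set.seed(36)
  vals <- c(rnorm(100, 1), rnorm(100, 0))
  out2 <- compare_bmi_halves(vals, groups)
  expect_equal(out2$test, "mannwhitney")
  expect_lt(out2$p_value, 0.001)
  ## constant equal values -> p = 1
  out3 <- compare_bmi_halves(rep(2, 200), groups)
  expect_equal(out3$p_value, 1)
  expect_error(compare_bmi_halves(vals, rep("[18.5,25)", 200)), "nonempty")
})

test_that("group_summaries computes stratified rates with CIs", {
  co <- generate_cohort(small_config(n_stays = 250, seed = 51))
  gs <- group_summaries(co, strata = "bmi_group",
                        metrics = c("mortality", "hypo_rate"),
                        B = 200, seed = 3)
  expect_true(all(gs$lower <= gs$estimate + 1e-12))
  expect_true(all(gs$upper >= gs$estimate - 1e-12))
  expect_true(all(gs$n > 0))
  ## mortality rate equals the direct proportion
  glyc <- glycemia_table(co)
  st <- co$stays[, list(stay_id, bmi, hospital_mortality)]
  st[, bmi_group := assign_bmi_group(bmi)]
  direct <- st[, mean(hospital_mortality), by = bmi_group]
  m <- gs[metric == "mortality"]
  expect_equal(m[direct, on = "bmi_group", estimate], direct$V1)
  ## top-quartile subset keeps ceiling(n/4) stays
  gs_tq <- group_summaries(co, glyc, strata = "bmi_group",
                           metrics = "hypo_rate",
                           subset = "top_quartile_monitoring",
                           B = 50, seed = 3)
  expect_equal(sum(gs_tq$n), ceiling(nrow(co$stays) / 4))
  ## hypoglycemic-only subset
  gs_h <- group_summaries(co, glyc, strata = "bmi_group",
                          metrics = "mortality", subset = "hypoglycemic",
                          B = 50, seed = 3)
  expect_equal(sum(gs_h$n), sum(glyc$any_hypo))
  expect_error(group_summaries(co, strata = "nope"), "unknown stratum")
  expect_error(group_summaries(co, metrics = "nope"), "unknown metric")
})

test_that("treatment exposures are clipped at first onset", {
  st <- data.frame(stay_id = "s1", database = "siteA", hospital_id = "h1",
                   age_years = 60, sex = "male", height_m = 1.8,
                   weight_kg = 80, bmi = NA, admission_type = "medical",
                   diabetes = NA, hba1c_pct = NA, los_icu_h = 40,
                   hospital_mortality = FALSE)
  meas <- data.frame(stay_id = "s1", variable = "glucose_mgdl",
                     time_h = c(0, 10, 20), value = c(120, 60, 110))
  rates <- data.frame(stay_id = "s1", drug = "insulin", start_h = 0,
                      end_h = 8, rate = 4, concentration_pct = NA_real_,
                      bolus = FALSE)
  flags <- data.frame(stay_id = "s1", exposure = "enteral_nutrition",
                      start_h = 0, end_h = 20)
  co <- icu_cohort(st, meas, rates, flags)
  out <- treatment_exposure_summary(co, B = 50, seed = 1)
  ## onset at 10 h: EN exposure [0, 20] clipped to 10 h
  expect_equal(out[metric == "en_duration_h", estimate], 10)
  expect_equal(out[metric == "insulin_max_uh", estimate], 4)
  expect_equal(out[metric == "insulin_max_uhkg", estimate], 0.05)
  expect_equal(out[metric == "pn_duration_h", estimate], 0)
  expect_equal(out[metric == "dextrose_mean_mlh", estimate], 0)
})
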