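## Model fitting and statistical machinery: pooled logistic regression
## on the window records (a discrete-time hazard model), Fox-Monette
## generalized variance-inflation factors, likelihood-ratio chi-square
## for categorical terms, percentile bootstrap CIs, and the univariate
## group summaries.

Z95 <- 1.959964

## Expand a design_table into a numeric model matrix with intercept.
## Indicator columns are named "term=level"; binary and continuous
## terms keep their own name. Returns the matrix plus a term map.
design_matrix <- function(design, drop_terms = character()) {
  referents <- attr(design, "referents")
  terms <- list()
  cols <- list(`(Intercept)` = rep(1, nrow(design)))
  add_factor <- function(name) {
    x <- design[[name]]
    if (!is.factor(x)) x <- factor(x)
    present <- levels(x)[tabulate(x, nbins = nlevels(x)) > 0L]
    empty <- setdiff(levels(x), present)
    if (length(empty)) {
      warning(sprintf("term %s: dropping empty level(s): %s", name,
                      paste(empty, collapse = ", ")), call. = FALSE)
    }
    ref <- referents[[name]]
    if (!ref %in% present) ref <- present[1L]
    for (lv in setdiff(present, ref)) {
      cols[[paste0(name, "=", lv)]] <<- as.numeric(x == lv)
      terms[[length(terms) + 1L]] <<- list(term = name, level = lv)
    }
  }
  add_plain <- function(name) {
    cols[[name]] <<- as.numeric(design[[name]])
    terms[[length(terms) + 1L]] <<- list(term = name, level = "")
  }
  factor_terms <- c("bmi_group", "glucose_bin", "insulin_bin",
                    "lactate_bin", "dextrose_bin", "database")
  plain_terms <- c("shock", "pn", "en", "steroids", "diabetes",
                   "sofa_no_cardio")
  for (nm in setdiff(factor_terms, drop_terms)) {
    if (nm %in% names(design)) add_factor(nm)
  }
  for (nm in setdiff(plain_terms, drop_terms)) {
    if (nm %in% names(design)) add_plain(nm)
  }
  X <- do.call(cbind, cols)
  term_map <- data.table::rbindlist(terms)
  term_map[, col := colnames(X)[-1L]]
  list(X = X, y = as.integer(design$H), term_map = term_map)
}

logistic_mle <- function(X, y) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(maxit = 100)))
  if (fit$rank < ncol(X)) {
    piv <- fit$qr$pivot
    alias <- colnames(X)[piv[(fit$rank + 1L):ncol(X)]]
    stop("singular design; aliased column(s): ",
         paste(alias, collapse = ", "), call. = FALSE)
  }
  ## complete separation: every observation perfectly predicted. A level
  ## with zero events (quasi-separation) is kept: its coefficient
  ## diverges towards -Inf with a huge SE, as in a plain glm() fit.
  mu <- fit$fitted.values
  if (all(mu[y == 1] > 0.999) && all(mu[y == 0] < 0.001)) {
    coefs <- fit$coefficients[-1L]
    culprit <- names(coefs)[which.max(abs(coefs))]
    stop("complete separation in the design (separating term: ",
         culprit, ")", call. = FALSE)
  }
  if (!fit$converged) {
    stop("logistic fit did not converge", call. = FALSE)
  }
  p1 <- seq_len(fit$rank)
  cov <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  nm <- colnames(X)[fit$qr$pivot[p1]]
  dimnames(cov) <- list(nm, nm)
  cov <- cov[colnames(X), colnames(X)]
  list(coef = fit$coefficients[colnames(X)], vcov = cov,
       deviance = fit$deviance, n = length(y))
}

#' Fit the pooled discrete-time logistic hazard model
#'
#' Maximum-likelihood logistic regression of the window outcome H on
#' the binned covariates, binary exposures, SOFA score without the
#' cardiovascular component (continuous) and the database indicator.
#' Wald 95% CIs are exp(beta +/- 1.959964 * SE). Covariate levels with
#' no records are dropped with a warning; separation and singular
#' designs raise errors naming the offending term.
#'
#' @param design A `design_table` from [assemble_design()].
#' @param compute_chi2 Compute the BMI likelihood-ratio chi-square
#'   (refits the reduced model; set FALSE in tight simulation loops).
#' @param cluster_se Use cluster-robust (sandwich) standard errors with
#'   stays as clusters, accounting for repeated windows per patient.
#'   Off by default: the replicated design pools windows plainly.
#' @return An object of class `hazard_fit` with elements `coef`, `vcov`,
#'   `or_table` (term, level, or, lo, hi, p), `gvif_table`, `bmi_chi2`
#'   (statistic, df, p), `n_records`, `n_events`.
#' @export
fit_pooled_logistic <- function(design, compute_chi2 = TRUE,
                                cluster_se = FALSE) {
  if (sum(design$H) < 1L || sum(design$H) == nrow(design)) {
    stop("fit_pooled_logistic: need at least one event and one non-event",
         call. = FALSE)
  }
  if (cluster_se && !"stay_id" %in% names(design)) {
    stop("cluster_se requires a stay_id column", call. = FALSE)
  }
  dm <- design_matrix(design)
  fit <- logistic_mle(dm$X, dm$y)
  if (cluster_se) {
    mu <- stats::plogis(drop(dm$X %*% fit$coef))
    score <- dm$X * (dm$y - mu)
    g <- rowsum(score, group = design$stay_id)
    G <- nrow(g)
    meat <- crossprod(g) * G / (G - 1)
    fit$vcov <- fit$vcov %*% meat %*% fit$vcov
  }
  est <- fit$coef[dm$term_map$col]
  se <- sqrt(diag(fit$vcov))[dm$term_map$col]
  or_table <- data.table::data.table(
    term = dm$term_map$term, level = dm$term_map$level,
    log_or = est, se = se,
    or = exp(est), lo = exp(est - Z95 * se), hi = exp(est + Z95 * se),
    p = 2 * stats::pnorm(-abs(est / se)))
  or_table[, key := dm$term_map$col]
  data.table::setcolorder(or_table, c("term", "level", "key"))
  gvif_table <- gvif_from_matrix(dm$X[, -1L, drop = FALSE], dm$term_map)
  bmi_chi2 <- if (compute_chi2 && "bmi_group" %in% dm$term_map$term) {
    lrt_term(design, "bmi_group", fit)
  } else {
    NULL
  }
  structure(list(coef = fit$coef, vcov = fit$vcov, or_table = or_table,
                 gvif_table = gvif_table, bmi_chi2 = bmi_chi2,
                 deviance = fit$deviance,
                 n_records = nrow(design), n_events = sum(design$H)),
            class = "hazard_fit")
}

#' @export
print.hazard_fit <- function(x, ...) {
  cat(sprintf("<hazard_fit> %d records, %d events\n",
              x$n_records, x$n_events))
  ot <- data.table::copy(x$or_table)
  ot[, `OR (95% CI)` := sprintf("%.2f (%.2f-%.2f)", or, lo, hi)]
  print(ot[, list(term, level, `OR (95% CI)`)], nrows = 50)
  if (!is.null(x$bmi_chi2)) {
    cat(sprintf("BMI chi2 = %.2f (df = %d), p = %.3g\n",
                x$bmi_chi2$statistic, x$bmi_chi2$df, x$bmi_chi2$p))
  }
  invisible(x)
}

lrt_term <- function(design, term, full_fit) {
  dm_red <- design_matrix(design, drop_terms = term)
  red <- logistic_mle(dm_red$X, as.integer(design$H))
  dm_full_p <- ncol(design_matrix(design)$X)
  stat <- red$deviance - full_fit$deviance
  df <- dm_full_p - ncol(dm_red$X)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Likelihood-ratio chi-square for a categorical model term
#'
#' 2 * (loglik_full - loglik_reduced) compared to a chi-square with as
#' many degrees of freedom as non-referent levels of the term.
#'
#' @param design A `design_table`.
#' @param term Term name (default `"bmi_group"`).
#' @return List with `statistic`, `df`, `p`.
#' @export
categorical_chi2 <- function(design, term = "bmi_group") {
  dm <- design_matrix(design)
  if (!term %in% dm$term_map$term) stop("unknown term: ", term,
                                        call. = FALSE)
  full <- logistic_mle(dm$X, dm$y)
  lrt_term(design, term, full)
}

## Fox-Monette GVIF from the centered predictor correlation matrix:
## GVIF_j = det(R_jj) det(R_(-j)(-j)) / det(R).
gvif_from_matrix <- function(X, term_map) {
  keep <- apply(X, 2L, stats::sd) > 0
  if (any(!keep)) {
    stop("gvif: constant predictor column(s): ",
         paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
  }
  R <- stats::cor(X)
  detR <- det(R)
  if (detR <= 0) stop("gvif: rank-deficient predictor matrix",
                      call. = FALSE)
  terms <- unique(term_map$term)
  out <- lapply(terms, function(tm) {
    j <- term_map$col[term_map$term == tm]
    g <- det(R[j, j, drop = FALSE]) *
      det(R[setdiff(colnames(R), j), setdiff(colnames(R), j),
            drop = FALSE]) / detR
    df <- length(j)
    data.table::data.table(term = tm, df = df, gvif = g,
                           gvif_adj = g^(1 / (2 * df)))
  })
  data.table::rbindlist(out)
}

#' Generalized variance-inflation factors of the hazard design
#'
#' @param design A `design_table` (or a `hazard_fit`, whose stored
#'   table is returned).
#' @return data.table with `term`, `df`, `gvif`, `gvif_adj`
#'   (GVIF^(1/(2 df))).
#' @export
gvif <- function(design) {
  if (inherits(design, "hazard_fit")) return(design$gvif_table)
  dm <- design_matrix(design)
  gvif_from_matrix(dm$X[, -1L, drop = FALSE], dm$term_map)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples the values with replacement `B` times and returns the
#' 2.5/97.5 percentiles of the resampled means. Deterministic given
#' `seed` (the caller's RNG state is restored afterwards).
#'
#' @param values Numeric (or logical) vector, length >= 1.
#' @param B Number of bootstrap repetitions (default 500).
#' @param seed Optional integer seed.
#' @return List with `mean`, `lower`, `upper`, `n`.
#' @export
bootstrap_mean_ci <- function(values, B = 500, seed = NULL) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  n <- length(values)
  if (!n) stop("bootstrap_mean_ci: no finite values", call. = FALSE)
  means <- with_seed(seed, {
    idx <- sample.int(n, n * B, replace = TRUE)
    rowMeans(matrix(values[idx], nrow = B))
  })
  qs <- unname(stats::quantile(means, c(0.025, 0.975)))
  list(mean = mean(values), lower = qs[1L], upper = qs[2L], n = n)
}

#' Compare BMI < 25 against BMI >= 25
#'
#' Pearson chi-square (no continuity correction) on the 2x2 table for
#' binary variables; two-sided Mann-Whitney U (normal approximation)
#' for continuous variables.
#'
#' @param values Logical (binary) or numeric vector.
#' @param bmi_groups Factor/character of BMI group labels
#'   (`bmi_group_levels()`).
#' @return List with `test`, `statistic`, `p_value`.
#' @export
compare_bmi_halves <- function(values, bmi_groups) {
  low <- as.character(bmi_groups) %in% bmi_group_levels()[1:2]
  keep <- !is.na(values) & !is.na(low)
  values <- values[keep]; low <- low[keep]
  if (!any(low) || all(low)) {
    stop("compare_bmi_halves: both BMI halves must be nonempty",
         call. = FALSE)
  }
  if (is.logical(values)) {
    tab <- table(factor(low, c(TRUE, FALSE)),
                 factor(values, c(TRUE, FALSE)))
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(test = "chi2", statistic = unname(ht$statistic),
         p_value = unname(ht$p.value))
  } else {
    x <- values[low]; y <- values[!low]
    if (length(unique(values)) == 1L) {
      return(list(test = "mannwhitney",
                  statistic = length(x) * length(y) / 2, p_value = 1))
    }
    ht <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    list(test = "mannwhitney", statistic = unname(ht$statistic),
         p_value = unname(ht$p.value))
  }
}

## Per-stay analysis frame joining statics with glycemic summaries and
## all univariate stratifiers.
stay_frame <- function(cohort, glyc = NULL) {
  if (is.null(glyc)) glyc <- glycemia_table(cohort)
  st <- data.table::copy(cohort$stays)
  out <- glyc[st, on = "stay_id"]
  if ("i.los_icu_h" %in% names(out)) out[, i.los_icu_h := NULL]
  out[, bmi_group := assign_bmi_group(bmi)]
  out[, hba1c_group := factor(NA_character_, levels = hba1c_group_levels())]
  ok <- is.finite(out$hba1c_pct) & out$hba1c_pct > 0
  out[ok, hba1c_group := assign_hba1c_group(hba1c_pct)]
  out[, twa_bin := bin_twa(twa_glucose)]
  out[, cv_bin := bin_cv(cv_glucose)]
  out[, episode_bin := bin_episodes(n_episodes)]
  out[]
}

GROUP_METRICS <- c(mortality = "hospital_mortality", hypo_rate = "any_hypo",
                   twa_glucose = "twa_glucose", cv_glucose = "cv_glucose",
                   measurements_per_h = "measurements_per_h",
                   mean_gap_h = "mean_gap_h", hypo_load = "hypo_load",
                   lowest_glucose = "lowest_glucose",
                   n_episodes = "n_episodes")

#' Stratified univariate group summaries with bootstrap CIs
#'
#' Mean (or rate, for binary metrics) with a percentile bootstrap CI,
#' per stratum. Strata are any combination of `bmi_group`,
#' `admission_type`, `diabetes`, `hba1c_group`, `twa_bin`, `cv_bin` and
#' `episode_bin`; the subset can restrict to stays that experienced
#' hypoglycemia or to the top quartile of glucose-monitoring frequency
#' (ties broken by stay id).
#'
#' @param cohort An `icu_cohort`.
#' @param glyc Optional precomputed [glycemia_table()].
#' @param strata Character vector of stratifier column names.
#' @param metrics Metric names among `r paste(names(GROUP_METRICS),
#'   collapse = ", ")`.
#' @param subset `"all"`, `"hypoglycemic"` or
#'   `"top_quartile_monitoring"`.
#' @param B,seed Bootstrap repetitions and seed.
#' @return data.table with the strata columns, `metric`, `n`,
#'   `estimate`, `lower`, `upper`.
#' @export
group_summaries <- function(cohort, glyc = NULL, strata = "bmi_group",
                            metrics = c("mortality", "hypo_rate",
                                        "twa_glucose", "cv_glucose"),
                            subset = c("all", "hypoglycemic",
                                       "top_quartile_monitoring"),
                            B = 500, seed = NULL) {
  subset <- match.arg(subset)
  df <- stay_frame(cohort, glyc)
  bad <- setdiff(strata, names(df))
  if (length(bad)) stop("unknown stratum: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(metrics, names(GROUP_METRICS))
  if (length(bad)) stop("unknown metric: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (subset == "hypoglycemic") {
    df <- df[any_hypo == TRUE]
  } else if (subset == "top_quartile_monitoring") {
    df <- df[order(-measurements_per_h, stay_id)]
    df <- df[seq_len(ceiling(nrow(df) / 4))]
  }
  with_seed(seed, {
    out <- lapply(metrics, function(m) {
      col <- GROUP_METRICS[[m]]
      d <- df[!is.na(get(col))]
      d[, {
        b <- bootstrap_mean_ci(get(col), B = B)
        list(metric = m, n = b$n, estimate = b$mean,
             lower = b$lower, upper = b$upper)
      }, by = strata]
    })
    data.table::rbindlist(out)[do.call(order, mget(strata))]
  })
}

#' Treatment exposure summary per BMI group
#'
#' Per BMI group: mean of the per-stay maximal hourly insulin dose
#' (u/h, and weight-adjusted u/h/kg), mean dextrose-10-equivalent
#' infusion rate (mL/h, time-averaged) and mean exposure durations (h)
#' of parenteral/enteral nutrition and corticosteroids. All quantities
#' are computed on the pre-first-hypoglycemia-onset part of the stay.
#'
#' @param cohort An `icu_cohort`.
#' @param glyc Optional precomputed [glycemia_table()].
#' @param B,seed Bootstrap repetitions and seed for the CIs.
#' @return data.table with `bmi_group`, `metric`, `n`, `estimate`,
#'   `lower`, `upper`.
#' @export
treatment_exposure_summary <- function(cohort, glyc = NULL, B = 500,
                                       seed = NULL) {
  df <- stay_frame(cohort, glyc)
  df[, t_end := pmin(los_icu_h, first_onset_h, na.rm = TRUE)]
  ends <- stats::setNames(df$t_end, df$stay_id)

  ins <- cohort$rates[drug == "insulin"]
  max_ins <- vapply(df$stay_id, function(id) {
    iv <- ins[stay_id == id]
    e <- ends[[id]]
    if (!nrow(iv) || e <= 0) return(0)
    nb <- ceiling(e)
    max(0, insulin_bin_doses(iv, bins_lo = 0:(nb - 1L), bins_hi = 1:nb))
  }, numeric(1))

  dex <- cohort$rates[drug == "dextrose" & concentration_pct != 5]
  mean_dex <- vapply(df$stay_id, function(id) {
    iv <- dex[stay_id == id]
    e <- ends[[id]]
    if (!nrow(iv) || e <= 0) return(0)
    ov <- pmax(0, pmin(iv$end_h, e) - pmax(iv$start_h, 0))
    sum(ov * iv$rate * iv$concentration_pct / 10) / e
  }, numeric(1))

  dur_of <- function(expo) {
    fl <- cohort$flags[exposure == expo]
    vapply(df$stay_id, function(id) {
      iv <- fl[stay_id == id]
      e <- ends[[id]]
      if (!nrow(iv) || e <= 0) return(0)
      sum(pmax(0, pmin(iv$end_h, e) - pmax(iv$start_h, 0)))
    }, numeric(1))
  }

  met <- data.table::data.table(
    stay_id = df$stay_id, bmi_group = df$bmi_group,
    insulin_max_uh = max_ins,
    insulin_max_uhkg = max_ins / df$weight_kg,
    dextrose_mean_mlh = mean_dex,
    pn_duration_h = dur_of("parenteral_nutrition"),
    en_duration_h = dur_of("enteral_nutrition"),
    steroid_duration_h = dur_of("corticosteroids"))
  long <- data.table::melt(met, id.vars = c("stay_id", "bmi_group"),
                           variable.name = "metric", variable.factor = FALSE)
  with_seed(seed, {
    long[!is.na(value), {
      b <- bootstrap_mean_ci(value, B = B)
      list(n = b$n, estimate = b$mean, lower = b$lower, upper = b$upper)
    }, by = list(bmi_group, metric)][order(bmi_group, metric)]
  })
}
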