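## Bespoke glycemic statistics: hypoglycemia detection, episode
## construction under the 6-hour termination rule, time-weighted average
## glucose (LOCF), coefficient of variation, hypoglycemic load and
## monitoring-frequency metrics.

HYPO_THRESHOLD_MGDL <- 70

as_series <- function(series) {
  if (is.numeric(series) && !is.null(dim(series))) {
    series <- data.frame(time_h = series[, 1L], value = series[, 2L])
  }
  stopifnot(all(c("time_h", "value") %in% names(series)))
  series
}

check_sorted <- function(time_h) {
  if (is.unsorted(time_h, strictly = FALSE)) {
    stop("glucose series must be sorted by time", call. = FALSE)
  }
}

#' Detect hypoglycemic measurements
#'
#' Returns the times of all glucose measurements at or below the
#' hypoglycemia threshold (inclusive: a value of exactly 70 mg/dL is an
#' event).
#'
#' @param series data.frame with columns `time_h`, `value` (mg/dL),
#'   sorted by time.
#' @param threshold Hypoglycemia threshold in mg/dL; default 70.
#' @return Numeric vector of event times (possibly empty).
#' @export
detect_hypo <- function(series, threshold = HYPO_THRESHOLD_MGDL) {
  series <- as_series(series)
  check_sorted(series$time_h)
  series$time_h[series$value <= threshold]
}

#' Build maximal hypoglycemia episodes
#'
#' A hypoglycemic measurement opens an episode that provisionally ends
#' 6 h later. A later hypoglycemic measurement inside the open episode
#' prolongs it (new provisional end 6 h after that measurement); a
#' non-hypoglycemic measurement inside the open episode terminates it at
#' the time of that measurement; otherwise the episode ends at its
#' provisional end. Episodes are truncated at discharge.
#'
#' @inheritParams detect_hypo
#' @param discharge_h ICU discharge time (hours); episodes are clipped to
#'   `[0, discharge_h]`.
#' @return An object of class `episode_set`: a data.table with columns
#'   `start_h`, `end_h`, `n_hypo_measurements`, plus attribute
#'   `first_onset_h` (NA if no episode).
#' @export
build_episodes <- function(series, discharge_h = Inf,
                           threshold = HYPO_THRESHOLD_MGDL) {
  series <- as_series(series)
  check_sorted(series$time_h)
  t <- series$time_h
  v <- series$value
  starts <- ends <- numeric(0)
  counts <- integer(0)
  open_start <- NA_real_
  prov_end <- NA_real_
  n_in <- 0L
  close <- function(end) {
    starts[length(starts) + 1L] <<- open_start
    ends[length(ends) + 1L] <<- min(end, discharge_h)
    counts[length(counts) + 1L] <<- n_in
    open_start <<- NA_real_
    n_in <<- 0L
  }
  for (i in seq_along(t)) {
    if (!is.na(open_start) && t[i] >= prov_end) close(prov_end)
    if (v[i] <= threshold) {
      if (is.na(open_start)) open_start <- t[i]
      prov_end <- t[i] + 6
      n_in <- n_in + 1L
    } else if (!is.na(open_start)) {
      close(t[i])
    }
  }
  if (!is.na(open_start)) close(prov_end)
  out <- data.table::data.table(start_h = starts, end_h = ends,
                                n_hypo_measurements = counts)
  structure(out, class = c("episode_set", class(out)),
            first_onset_h = if (nrow(out)) out$start_h[1L] else NA_real_)
}

#' @export
print.episode_set <- function(x, ...) {
  cat(sprintf("<episode_set> %d episode(s); first onset at %s h\n",
              nrow(x), format(attr(x, "first_onset_h"))))
  if (nrow(x)) print(data.table::as.data.table(x))
  invisible(x)
}

#' Time-weighted average glucose (LOCF step integral)
#'
#' Integrates the last-observation-carried-forward step function of the
#' glucose series from the first measurement to `window_end_h` and divides
#' by the elapsed duration. With a single usable measurement (or a
#' zero-length span) the value itself is returned. Measurements after
#' `window_end_h` are ignored; in the study design the window ends at the
#' earlier of discharge and first hypoglycemia onset.
#'
#' @inheritParams detect_hypo
#' @param window_end_h End of the averaging window (hours).
#' @return TWA glucose in mg/dL, or NA if no measurement falls at or
#'   before `window_end_h`.
#' @export
twa_glucose <- function(series, window_end_h) {
  series <- as_series(series)
  check_sorted(series$time_h)
  keep <- series$time_h <= window_end_h
  t <- series$time_h[keep]
  v <- series$value[keep]
  if (!length(t)) return(NA_real_)
  span <- window_end_h - t[1L]
  if (span <= 0) return(v[length(v)])   # zero-length span: value at the end
  if (length(t) == 1L) return(v[1L])
  widths <- diff(c(t, window_end_h))
  sum(widths * v) / span
}

#' Coefficient of variation of glucose, in percent
#'
#' 100 * sample SD / mean of the raw (unweighted) measurement values in
#' the window.
#'
#' @inheritParams twa_glucose
#' @return CV in percent, or NA with fewer than two measurements.
#' @export
cv_glucose <- function(series, window_end_h = Inf) {
  series <- as_series(series)
  v <- series$value[series$time_h <= window_end_h]
  if (length(v) < 2L) return(NA_real_)
  100 * stats::sd(v) / mean(v)
}

#' Hypoglycemic load
#'
#' Proportion of glucose measurements at or below the threshold.
#'
#' @inheritParams twa_glucose
#' @export
hypo_load <- function(series, threshold = HYPO_THRESHOLD_MGDL,
                      window_end_h = Inf) {
  series <- as_series(series)
  v <- series$value[series$time_h <= window_end_h]
  if (!length(v)) return(NA_real_)
  mean(v <= threshold)
}

#' Glucose monitoring frequency
#'
#' @inheritParams detect_hypo
#' @param los_icu_h Length of ICU stay in hours (> 0).
#' @return List with `per_hour` (measurements per hour of stay) and
#'   `mean_gap_h` (mean gap between successive measurements; NA if < 2).
#' @export
monitoring_frequency <- function(series, los_icu_h) {
  stopifnot(los_icu_h > 0)
  series <- as_series(series)
  n <- nrow(series)
  list(per_hour = n / los_icu_h,
       mean_gap_h = if (n >= 2L) mean(diff(series$time_h)) else NA_real_)
}

#' Per-stay glycemic summary
#'
#' Combines the glycemic statistics for one stay. TWA and CV are computed
#' on the window ending at the earlier of discharge and first hypoglycemia
#' onset (`cv_window = "pre_onset"`, the default) or on the whole stay
#' (`"full"`). Hypoglycemic load and lowest glucose are computed over the
#' whole stay, as used for severity analyses of the hypoglycemic cohort.
#'
#' @param stay One-row data.frame (or list) with at least `stay_id` and
#'   `los_icu_h`.
#' @param series The stay's glucose series.
#' @param threshold Hypoglycemia threshold (mg/dL).
#' @param cv_window `"pre_onset"` or `"full"`.
#' @return One-row data.table (a `GlycemicSummary`).
#' @export
summarize_glycemia <- function(stay, series,
                               threshold = HYPO_THRESHOLD_MGDL,
                               cv_window = c("pre_onset", "full")) {
  cv_window <- match.arg(cv_window)
  series <- as_series(series)
  eps <- build_episodes(series, discharge_h = stay$los_icu_h,
                        threshold = threshold)
  onset <- attr(eps, "first_onset_h")
  w_end <- min(stay$los_icu_h, onset, na.rm = TRUE)
  cv_end <- if (cv_window == "pre_onset") w_end else stay$los_icu_h
  mf <- monitoring_frequency(series, stay$los_icu_h)
  data.table::data.table(
    stay_id = stay$stay_id,
    twa_glucose = twa_glucose(series, w_end),
    cv_glucose = cv_glucose(series, cv_end),
    n_measurements = nrow(series),
    measurements_per_h = mf$per_hour,
    mean_gap_h = mf$mean_gap_h,
    hypo_load = hypo_load(series, threshold),
    lowest_glucose = if (nrow(series)) min(series$value) else NA_real_,
    n_episodes = nrow(eps),
    first_onset_h = onset,
    any_hypo = nrow(eps) >= 1L)
}

#' Glycemic summaries for every stay in a cohort
#'
#' @param cohort An `icu_cohort`.
#' @inheritParams summarize_glycemia
#' @return data.table with one `GlycemicSummary` row per stay.
#' @export
glycemia_table <- function(cohort, threshold = HYPO_THRESHOLD_MGDL,
                           cv_window = c("pre_onset", "full")) {
  cv_window <- match.arg(cv_window)
  stopifnot(inherits(cohort, "icu_cohort"))
  glu <- cohort$measurements[variable == "glucose_mgdl"]
  los <- cohort$stays[, list(stay_id, los_icu_h)]
  out <- glu[los, on = "stay_id"][
    , summarize_one(time_h, value, los_icu_h[1L], threshold, cv_window),
    by = stay_id]
  out[los, on = "stay_id"][order(stay_id)]
}

## Core of summarize_glycemia on bare vectors; used for the cohort-wide
## by-stay computation (avoids per-stay data.frame construction).
summarize_one <- function(t, v, los, threshold, cv_window) {
  if (length(t) == 1L && is.na(t)) {          # stay with no glucose rows
    return(list(twa_glucose = NA_real_, cv_glucose = NA_real_,
                n_measurements = 0L, measurements_per_h = 0,
                mean_gap_h = NA_real_, hypo_load = NA_real_,
                lowest_glucose = NA_real_, n_episodes = 0L,
                first_onset_h = NA_real_, any_hypo = FALSE))
  }
  s <- data.frame(time_h = t, value = v)
  eps <- build_episodes(s, discharge_h = los, threshold = threshold)
  onset <- attr(eps, "first_onset_h")
  w_end <- min(los, onset, na.rm = TRUE)
  cv_end <- if (cv_window == "pre_onset") w_end else los
  list(twa_glucose = twa_glucose(s, w_end),
       cv_glucose = cv_glucose(s, cv_end),
       n_measurements = length(t),
       measurements_per_h = length(t) / los,
       mean_gap_h = if (length(t) >= 2L) mean(diff(t)) else NA_real_,
       hypo_load = mean(v <= threshold),
       lowest_glucose = min(v),
       n_episodes = nrow(eps),
       first_onset_h = onset,
       any_hypo = nrow(eps) >= 1L)
}
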