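## Canonical level sets for every binned covariate used in the analysis.
## Bins are left-closed right-open unless the clinical convention is
## inclusive (hypoglycemia "<= 70"; HbA1c 6.1-6.5 closed on both ends).

#' Canonical BMI group labels (WHO cut-points)
#'
#' Six groups partitioning (0, Inf) at 18.5, 25, 30, 35 and 40 kg/m^2,
#' left-closed right-open.
#'
#' @return Character vector of the six labels in increasing BMI order.
#' @export
bmi_group_levels <- function() {
  c("[0,18.5)", "[18.5,25)", "[25,30)", "[30,35)", "[35,40)", ">=40")
}

#' @rdname bmi_group_levels
#' @export
hba1c_group_levels <- function() {
  c("<6.1", "[6.1,6.5]", "(6.5,7.0]", ">7.0")
}

#' @rdname bmi_group_levels
#' @export
glucose_bin_levels <- function() {
  c("[70,108)", "[108,144)", "[144,180)", ">=180")
}

#' @rdname bmi_group_levels
#' @export
insulin_bin_levels <- function() {
  c("0", "(0,2.5]", "(2.5,5]", ">5")
}

#' @rdname bmi_group_levels
#' @export
lactate_bin_levels <- function() {
  c("[0,2)", "[2,5)", ">=5")
}

#' @rdname bmi_group_levels
#' @export
dextrose_bin_levels <- function() {
  c("0", "(0,25)", ">=25")
}

#' @rdname bmi_group_levels
#' @export
twa_bin_levels <- function() {
  c("[70,140)", "[140,180)", ">=180")
}

#' @rdname bmi_group_levels
#' @export
cv_bin_levels <- function() {
  c("<10", "[10,20)", "[20,30)", ">=30")
}

#' @rdname bmi_group_levels
#' @export
episode_bin_levels <- function() {
  c("0", "1", ">1")
}

#' Convert glucose concentration from mmol/L to mg/dL
#'
#' Uses the molar mass of glucose, 18.016 mg/dL per mmol/L, so that the
#' usual clinical threshold pairing (3.9 mmol/L ~ 70 mg/dL) holds after
#' rounding.
#'
#' @param value Numeric vector of non-negative concentrations in mmol/L.
#' @return Numeric vector in mg/dL.
#' @examples
#' mmoll_to_mgdl(3.9)   # 70.26
#' @export
mmoll_to_mgdl <- function(value) {
  if (!is.numeric(value) || any(!is.finite(value)) || any(value < 0)) {
    stop("mmoll_to_mgdl: value must be finite and >= 0", call. = FALSE)
  }
  value * 18.016
}

#' Assign WHO BMI groups
#'
#' @param bmi Numeric vector of BMI values in kg/m^2, all finite and > 0.
#' @return Factor with levels `bmi_group_levels()`.
#' @examples
#' assign_bmi_group(c(24.9, 25, 43.7))
#' @export
assign_bmi_group <- function(bmi) {
  if (!is.numeric(bmi) || any(!is.finite(bmi)) || any(bmi <= 0)) {
    stop("assign_bmi_group: bmi must be finite and > 0", call. = FALSE)
  }
  cut(bmi, breaks = c(0, 18.5, 25, 30, 35, 40, Inf),
      labels = bmi_group_levels(), right = FALSE)
}

#' Assign HbA1c control groups
#'
#' Groups: non-diabetic (< 6.1%), pre-diabetic (6.1-6.5%, closed on both
#' ends), controlled diabetes (6.6-7.0%, represented as (6.5, 7.0]) and
#' poorly controlled diabetes (> 7.0%).
#'
#' @param hba1c Numeric vector of HbA1c percentages, finite and > 0.
#' @return Factor with levels `hba1c_group_levels()`.
#' @export
assign_hba1c_group <- function(hba1c) {
  if (!is.numeric(hba1c) || any(!is.finite(hba1c)) || any(hba1c <= 0)) {
    stop("assign_hba1c_group: hba1c must be finite and > 0", call. = FALSE)
  }
  lv <- hba1c_group_levels()
  out <- ifelse(hba1c < 6.1, lv[1L],
         ifelse(hba1c <= 6.5, lv[2L],
         ifelse(hba1c <= 7.0, lv[3L], lv[4L])))
  factor(out, levels = lv)
}

## Internal binning helpers used when building the design table.

## fast integer cut onto ordered levels (findInterval keeps factor codes)
bin_glucose <- function(x) {
  lv <- glucose_bin_levels()
  structure(findInterval(x, c(-Inf, 108, 144, 180)), levels = lv,
            class = "factor")
}

bin_insulin <- function(x) {
  lv <- insulin_bin_levels()
  structure(findInterval(x, c(0, 2.5, 5), left.open = TRUE) + 1L,
            levels = lv, class = "factor")
}

bin_lactate <- function(x) {
  lv <- lactate_bin_levels()
  structure(findInterval(x, c(-Inf, 2, 5)), levels = lv, class = "factor")
}

bin_dextrose <- function(x) {
  lv <- dextrose_bin_levels()
  code <- findInterval(x, c(-Inf, 25))
  code[x <= 0] <- 0L
  structure(code + 1L, levels = lv, class = "factor")
}

bin_twa <- function(x) {
  lv <- twa_bin_levels()
  out <- ifelse(x < 140, lv[1L], ifelse(x < 180, lv[2L], lv[3L]))
  out[!is.finite(x)] <- NA
  factor(out, levels = lv)
}

bin_cv <- function(x) {
  lv <- cv_bin_levels()
  out <- ifelse(x < 10, lv[1L],
         ifelse(x < 20, lv[2L],
         ifelse(x < 30, lv[3L], lv[4L])))
  out[!is.finite(x)] <- NA
  factor(out, levels = lv)
}

bin_episodes <- function(n) {
  lv <- episode_bin_levels()
  out <- ifelse(n == 0, lv[1L], ifelse(n == 1, lv[2L], lv[3L]))
  factor(out, levels = lv)
}
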