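#' HOMA-IR insulin resistance index
#'
#' `(fasting glucose [mmol/l] x fasting insulin [uU/ml]) / 22.5`, with
#' insulin converted from pmol/l at `pmol_per_uu` pmol/l per uU/ml.
#'
#' @param glucose fasting plasma glucose, mmol/l.
#' @param insulin fasting plasma insulin, pmol/l.
#' @param pmol_per_uu insulin unit conversion constant (default 6.0).
#' @return the HOMA-IR index (dimensionless).
#' @examples
#' homa_ir(5, 27) # 5 * 4.5 / 22.5 = 1
#' @export
homa_ir <- function(glucose, insulin, pmol_per_uu = 6.0) {
  check_positive(glucose, "glucose")
  check_positive(insulin, "insulin")
  glucose * (insulin / pmol_per_uu) / 22.5
}

#' Matsuda insulin sensitivity index
#'
#' `10000 / sqrt(G0 * I0 * Gmean * Imean)` with glucose in mg/dl and insulin
#' in uU/ml.  The means are trapezoidal time-weighted means over the full
#' test by default (`variant = "full"`, suited to the 180-min MMTT with its
#' non-uniform sampling grid); `variant = "classic120"` restricts them to
#' 0-120 min.
#'
#' @param time sampling times, minutes; must include 0.
#' @param glucose plasma glucose series, mmol/l.
#' @param insulin plasma insulin series, pmol/l.
#' @param variant `"full"` (default) or `"classic120"`.
#' @param pmol_per_uu insulin unit conversion constant (default 6.0).
#' @return the Matsuda index (dimensionless).
#' @export
matsuda <- function(time, glucose, insulin, variant = c("full", "classic120"),
                    pmol_per_uu = 6.0) {
  variant <- match.arg(variant)
  stopifnot(length(time) == length(glucose), length(time) == length(insulin))
  if (!any(time == 0)) stop("series must include a t = 0 sample")
  check_positive(glucose, "glucose")
  check_positive(insulin, "insulin")
  g_mgdl <- glucose * 18.016
  i_uu <- insulin / pmol_per_uu
  keep <- if (variant == "classic120") time <= 120 else rep(TRUE, length(time))
  g0 <- g_mgdl[time == 0][1]
  i0 <- i_uu[time == 0][1]
  gm <- trapz_mean(time[keep], g_mgdl[keep])
  im <- trapz_mean(time[keep], i_uu[keep])
  10000 / sqrt(g0 * i0 * gm * im)
}

#' Insulin clearance from secretion and insulin levels
#'
#' Fasting clearance is the ratio of basal secretion to fasting insulin,
#' `ISR(0) / I(0)`; total clearance is the ratio of the trapezoidal AUCs of
#' ISR and insulin over the test.  With ISR in pmol/min and insulin in
#' pmol/l both are on the scale of l/min.
#'
#' @param isr an [isr_trace()].
#' @param insulin_time insulin sampling times, minutes.
#' @param insulin plasma insulin, pmol/l.
#' @param mode `"fasting"` or `"total"`.
#' @return clearance, l/min.
#' @export
insulin_clearance <- function(isr, insulin_time, insulin,
                              mode = c("fasting", "total")) {
  mode <- match.arg(mode)
  if (!inherits(isr, "isr_trace")) stop("'isr' must be an isr_trace")
  stopifnot(length(insulin_time) == length(insulin))
  check_positive(insulin, "insulin")
  if (mode == "fasting") {
    i0 <- insulin[which.min(insulin_time)]
    isr0 <- isr$isr[which.min(isr$time)]
    if (i0 <= 0) stop("zero fasting insulin")
    return(isr0 / i0)
  }
  lo <- max(min(isr$time), min(insulin_time))
  hi <- min(max(isr$time), max(insulin_time))
  if (hi <= lo) stop("no overlapping time support for total clearance")
  keep_i <- insulin_time >= lo & insulin_time <= hi
  keep_s <- isr$time >= lo & isr$time <= hi
  auc_i <- auc_trapezoid(insulin_time[keep_i], insulin[keep_i])
  if (auc_i <= 0) stop("zero insulin AUC")
  auc_trapezoid(isr$time[keep_s], isr$isr[keep_s]) / auc_i
}

#' Fatty liver index
#'
#' Logistic steatosis score
#' `y = 0.953*ln(TG) + 0.139*BMI + 0.718*ln(GGT) + 0.053*waist - 15.745`,
#' `FLI = exp(y)/(1+exp(y)) * 100`, with triglycerides in mg/dl and GGT in
#' IU/l (triglycerides given in mmol/l are converted internally at 88.57
#' mg/dl per mmol/l).
#'
#' @param triglycerides serum triglycerides.
#' @param bmi body mass index, kg/m^2.
#' @param ggt gamma-glutamyl transferase, IU/l.
#' @param waist waist circumference, cm.
#' @param tg_units `"mg_dl"` (default) or `"mmol_l"`.
#' @return score in (0, 100).
#' @export
fatty_liver_index <- function(triglycerides, bmi, ggt, waist,
                              tg_units = c("mg_dl", "mmol_l")) {
  tg_units <- match.arg(tg_units)
  check_positive(triglycerides, "triglycerides")
  check_positive(bmi, "bmi")
  check_positive(ggt, "ggt")
  check_positive(waist, "waist")
  tg <- if (tg_units == "mmol_l") triglycerides * 88.57 else triglycerides
  y <- 0.953 * log(tg) + 0.139 * bmi + 0.718 * log(ggt) +
    0.053 * waist - 15.745
  exp(y) / (1 + exp(y)) * 100
}

#' HbA1c unit conversions
#'
#' The IFCC (mmol/mol) and NGSP (%) HbA1c reporting scales are related by the
#' affine master equation `NGSP = 0.09148 * IFCC + 2.152`.  The forward
#' conversion rounds half-up to one decimal for display, matching clinical
#' reporting; set `round = FALSE` for the raw value.
#'
#' @param ifcc HbA1c in mmol/mol, between 20 and 200.
#' @param round round to one decimal (default TRUE).
#' @return HbA1c in percent.
#' @examples
#' hba1c_ifcc_to_ngsp(49) # 6.6
#' @export
hba1c_ifcc_to_ngsp <- function(ifcc, round = TRUE) {
  if (any(!is.finite(ifcc)) || any(ifcc < 20) || any(ifcc > 200)) {
    stop("'ifcc' must be within 20-200 mmol/mol")
  }
  pct <- 0.09148 * ifcc + 2.152
  if (round) round_half_up(pct, 1) else pct
}

#' @rdname hba1c_ifcc_to_ngsp
#' @param ngsp HbA1c in percent.
#' @export
hba1c_ngsp_to_ifcc <- function(ngsp) {
  check_positive(ngsp, "ngsp")
  (ngsp - 2.152) / 0.09148
}

#' Macronutrient energy fractions of a meal
#'
#' Percentage of a meal's stated total energy contributed by each
#' macronutrient, from Atwater factors (carbohydrate and protein 4 kcal/g,
#' fat 9 kcal/g, at 4.184 kJ/kcal).  Fractions are reported against the
#' stated total energy and are not forced to sum to 100, since label totals
#' may be internally inconsistent.
#'
#' @param carb_g,fat_g,protein_g grams of each macronutrient.
#' @param energy_kj stated total energy of the meal, kJ.
#' @param digits decimals for rounding (half-up); `NULL` for raw values.
#' @return named numeric vector (`carb`, `fat`, `protein`), percent.
#' @examples
#' energy_fractions(37, 12, 12, 1255) # carb 49.3, protein 16.0
#' @export
energy_fractions <- function(carb_g, fat_g, protein_g, energy_kj,
                             digits = 1) {
  check_nonnegative(c(carb_g, fat_g, protein_g), "grams")
  check_positive(energy_kj, "energy_kj")
  kj_per_g <- c(carb = 4, fat = 9, protein = 4) * 4.184
  pct <- c(carb = carb_g, fat = fat_g, protein = protein_g) *
    kj_per_g / energy_kj * 100
  if (is.null(digits)) pct else round_half_up(pct, digits)
}

#' Harris-Benedict resting energy expenditure
#'
#' Classic Harris-Benedict equations (kcal/day, converted to kJ/day):
#' men `66.473 + 13.7516 w + 5.0033 h - 6.755 a`, women
#' `655.0955 + 9.5634 w + 1.8496 h - 4.6756 a` with weight in kg, height in
#' cm and age in years.
#'
#' @param sex `"M"` or `"F"`.
#' @param age years.
#' @param weight_kg body weight, kg.
#' @param height_cm height, cm.
#' @return resting energy expenditure, kJ/day.
#' @export
harris_benedict <- function(sex = c("M", "F"), age, weight_kg, height_cm) {
  sex <- match.arg(sex)
  check_positive(age, "age")
  check_positive(weight_kg, "weight_kg")
  check_positive(height_cm, "height_cm")
  kcal <- if (sex == "M") {
    66.4730 + 13.7516 * weight_kg + 5.0033 * height_cm - 6.7550 * age
  } else {
    655.0955 + 9.5634 * weight_kg + 1.8496 * height_cm - 4.6756 * age
  }
  kcal * 4.184
}

#' Energy prescription for a weight-loss diet
#'
#' Daily energy prescription: Harris-Benedict resting expenditure plus
#' physical-activity expenditure, minus the constant daily deficit needed for
#' a cumulative deficit of `target_loss_fraction * weight * 32220` kJ over
#' `weeks` weeks (32,220 kJ ~ 7,700 kcal per kg of body tissue, a documented
#' energy-density convention).
#'
#' @inheritParams harris_benedict
#' @param activity_kj daily physical-activity energy expenditure, kJ.
#' @param target_loss_fraction fractional body-weight loss target over the
#'   prescription period, in `[0, 0.2)`.
#' @param weeks prescription length, weeks.
#' @param kj_per_kg body-tissue energy density, kJ/kg (default 32220).
#' @return a list with `prescription_kj`, `ree_kj`, `deficit_kj` (all per
#'   day) and a logical `below_80pct_ree` warning flag.
#' @export
energy_requirement <- function(sex, age, weight_kg, height_cm,
                               activity_kj = 0, target_loss_fraction = 0,
                               weeks = 12, kj_per_kg = 32220) {
  if (target_loss_fraction < 0 || target_loss_fraction >= 0.2) {
    stop("'target_loss_fraction' must be in [0, 0.2)")
  }
  check_nonnegative(activity_kj, "activity_kj")
  check_positive(weeks, "weeks")
  ree <- harris_benedict(sex, age, weight_kg, height_cm)
  deficit <- target_loss_fraction * weight_kg * kj_per_kg / (weeks * 7)
  rx <- ree + activity_kj - deficit
  flag <- rx < 0.8 * ree
  if (flag) warning("prescription falls below 80% of resting expenditure")
  list(prescription_kj = rx, ree_kj = ree, deficit_kj = deficit,
       below_80pct_ree = flag)
}
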