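#' Population C-peptide kinetic coefficient table
#'
#' Coefficients of the standard population two-exponential C-peptide kinetic
#' model used for deconvolution-based insulin secretion estimation.  For each
#' clinical class the plasma C-peptide impulse response is
#' `A * exp(-a*t) + B * exp(-b*t)` with amplitude fraction
#' `A/(A+B) = fraction`, short half-life `halflife_short` (min), long
#' half-life `hl_long_intercept + hl_long_age_slope * age` (min), and central
#' distribution volume `vol_intercept + vol_bsa_slope * BSA` (litres, Du Bois
#' body surface area).
#'
#' The table ships with the package as a documented asset and can be replaced
#' wholesale via the `coefficients` argument of [population_kinetics()] (for
#' instance with locally re-estimated values).
#'
#' @return a data.frame with one row per clinical class
#'   (`normal`, `obese`, `t2d`).
#' @seealso [population_kinetics()]
#' @export
kinetics_coefficients <- function() {
  data.frame(
    class = c("normal", "obese", "t2d"),
    fraction = c(0.76, 0.78, 0.78),
    halflife_short = c(4.95, 4.55, 4.52),
    hl_long_intercept = c(29.2, 29.2, 29.2),
    hl_long_age_slope = c(0.14, 0.14, 0.14),
    vol_intercept = c(0.64, 2.04, 2.04),
    vol_bsa_slope = c(1.92, 1.11, 1.11),
    stringsAsFactors = FALSE
  )
}

#' Two-compartment C-peptide kinetics
#'
#' Constructs the kinetic parameter set of the linear two-compartment
#' C-peptide model: irreversible loss `k01` from the central (plasma)
#' compartment, exchange rates `k21` (central to peripheral) and `k12`
#' (peripheral to central), and central distribution volume `V`.  At constant
#' secretion `S` the steady-state plasma concentration is `S / (k01 * V)`.
#'
#' @param k01 irreversible elimination rate from plasma, per min.
#' @param k12 peripheral-to-central exchange rate, per min.
#' @param k21 central-to-peripheral exchange rate, per min.
#' @param V central distribution volume, litres.
#' @return an object of class `cpeptide_kinetics`.
#' @examples
#' cpeptide_kinetics(k01 = 0.06, k12 = 0.05, k21 = 0.05, V = 3.5)
#' @export
cpeptide_kinetics <- function(k01, k12, k21, V) {
  check_positive(k01, "k01")
  check_positive(k12, "k12")
  check_positive(k21, "k21")
  check_positive(V, "V")
  kin <- structure(
    list(k01 = k01, k12 = k12, k21 = k21, V = V),
    class = "cpeptide_kinetics"
  )
  ev <- kinetics_eigenrates(kin)
  # fast/slow eigenrates must be distinct: terminal half-life > initial one
  if (ev["fast"] - ev["slow"] < 1e-10) {
    stop("degenerate kinetics: terminal half-life must exceed the initial one")
  }
  kin
}

# eigen decay rates (per min) of the two-compartment system, fast > slow > 0
kinetics_eigenrates <- function(kin) {
  s <- kin$k01 + kin$k12 + kin$k21
  p <- kin$k01 * kin$k12
  disc <- sqrt(max(s^2 / 4 - p, 0))
  c(fast = s / 2 + disc, slow = s / 2 - disc)
}

#' @export
print.cpeptide_kinetics <- function(x, ...) {
  ev <- kinetics_eigenrates(x)
  cat("C-peptide two-compartment kinetics\n")
  cat(sprintf("  k01 = %.4f, k12 = %.4f, k21 = %.4f per min; V = %.2f l\n",
              x$k01, x$k12, x$k21, x$V))
  cat(sprintf("  half-lives: %.1f min (initial), %.1f min (terminal)\n",
              log(2) / ev["fast"], log(2) / ev["slow"]))
  invisible(x)
}

#' Population C-peptide kinetics from anthropometrics
#'
#' Computes subject-specific two-compartment kinetic parameters from the
#' population regression on age, Du Bois body surface area and clinical class
#' (normal weight, obese, or type 2 diabetes).  The two-exponential
#' population parameters (amplitude fraction, short and long half-lives,
#' distribution volume) are converted to compartmental rate constants via the
#' standard relations for a bi-exponential impulse response `A e^{-at} +
#' B e^{-bt}` with `A + B = 1`:
#' `k12 = A*b + B*a`, `k01 = a*b / k12`, `k21 = a + b - k12 - k01`.
#'
#' @param age years, between 18 and 100.
#' @param sex `"M"` or `"F"`; recorded for provenance (the population
#'   regression itself is sex-independent).
#' @param height_cm standing height, cm.
#' @param weight_kg body weight, kg.
#' @param diabetes logical; type 2 diabetes present.
#' @param obese logical; BMI >= 30 without diabetes.
#' @param coefficients coefficient table in the layout of
#'   [kinetics_coefficients()].
#' @return a [cpeptide_kinetics()] object with attributes `class_used` and
#'   `bsa`.
#' @examples
#' population_kinetics(65, "M", 170, 80, diabetes = TRUE)
#' @export
population_kinetics <- function(age, sex = c("M", "F"), height_cm, weight_kg,
                                diabetes = TRUE, obese = FALSE,
                                coefficients = kinetics_coefficients()) {
  sex <- match.arg(sex)
  if (!is.numeric(age) || age < 18 || age > 100) {
    stop("'age' must be between 18 and 100 years")
  }
  if (height_cm < 100 || height_cm > 250) stop("'height_cm' out of range")
  if (weight_kg < 30 || weight_kg > 300) stop("'weight_kg' out of range")

  cls <- if (isTRUE(diabetes)) "t2d" else if (isTRUE(obese)) "obese" else "normal"
  row <- coefficients[coefficients$class == cls, , drop = FALSE]
  if (nrow(row) != 1L) stop("coefficient table lacks class ", cls)

  bsa <- body_surface_area(weight_kg, height_cm)
  a <- log(2) / row$halflife_short
  b <- log(2) / (row$hl_long_intercept + row$hl_long_age_slope * age)
  A <- row$fraction
  B <- 1 - A
  k12 <- A * b + B * a
  k01 <- a * b / k12
  k21 <- a + b - k12 - k01
  V <- row$vol_intercept + row$vol_bsa_slope * bsa

  kin <- cpeptide_kinetics(k01 = k01, k12 = k12, k21 = k21, V = V)
  attr(kin, "class_used") <- cls
  attr(kin, "bsa") <- bsa
  kin
}
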