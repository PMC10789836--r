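#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package functions never clobber the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Trapezoidal area under a sampled curve
#'
#' @param time numeric, strictly increasing sampling times.
#' @param value numeric, same length as `time`.
#' @return the trapezoidal integral of `value` over `time`.
#' @examples
#' auc_trapezoid(c(0, 60, 180), c(0, 10, 0)) # triangle: 900
#' @export
auc_trapezoid <- function(time, value) {
  stopifnot(length(time) == length(value), length(time) >= 2)
  if (any(diff(time) <= 0)) stop("'time' must be strictly increasing")
  sum(diff(time) * (head(value, -1) + tail(value, -1)) / 2)
}

# time-weighted (trapezoidal) mean of a sampled curve
trapz_mean <- function(time, value) {
  auc_trapezoid(time, value) / (max(time) - min(time))
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.05 -> 0.1), the convention used for
#' reporting HbA1c percentages and energy fractions, as opposed to the
#' round-half-even rule of [round()].
#'
#' @param x numeric.
#' @param digits number of decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# defensive scalar checks ---------------------------------------------------

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be finite and strictly positive", name),
         call. = FALSE)
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("'%s' must be finite and non-negative", name), call. = FALSE)
  }
  invisible(x)
}

# FNV-1a hash of a character scalar, returned as 8 hex digits; used to
# fingerprint resolved pipeline configurations in the run manifest.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor affects only the low byte since b < 256; keeps h a double
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime 16777619, done in doubles
    h <- (h * 16777619) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

#' Du Bois body surface area
#'
#' @param weight_kg body weight in kg.
#' @param height_cm height in cm.
#' @return body surface area in m^2.
#' @examples
#' body_surface_area(70, 170)
#' @export
body_surface_area <- function(weight_kg, height_cm) {
  check_positive(weight_kg, "weight_kg")
  check_positive(height_cm, "height_cm")
  0.007184 * weight_kg^0.425 * height_cm^0.725
}
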