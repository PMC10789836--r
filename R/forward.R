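#' Insulin secretion rate trace
#'
#' A sampled insulin secretion rate (ISR) curve on a uniform time grid, the
#' common currency between deconvolution, the beta cell model and the
#' metabolic indices.  ISR is interpreted as piecewise constant and
#' left-continuous: the value at grid point `i` applies over
#' `[time[i], time[i+1])`.
#'
#' @param time minutes, uniform strictly increasing grid.
#' @param isr pmol/min, non-negative, same length as `time`.
#' @param se optional pointwise standard errors.
#' @return an object of class `isr_trace` (a list with elements `time`,
#'   `isr`, `se`).
#' @export
isr_trace <- function(time, isr, se = NULL) {
  stopifnot(length(time) == length(isr), length(time) >= 2)
  dt <- diff(time)
  if (any(dt <= 0)) stop("'time' must be strictly increasing")
  if (max(dt) - min(dt) > 1e-8 * max(dt)) {
    stop("'time' must be a uniform grid")
  }
  check_nonnegative(isr, "isr")
  structure(list(time = as.numeric(time), isr = as.numeric(isr), se = se),
            class = "isr_trace")
}

#' @export
print.isr_trace <- function(x, ...) {
  cat(sprintf(
    "ISR trace: %d points over %g-%g min; peak %.1f pmol/min, AUC %.0f pmol\n",
    length(x$time), min(x$time), max(x$time), max(x$isr),
    auc_trapezoid(x$time, x$isr)))
  invisible(x)
}

# step-transition operators of the two-compartment system for step h:
#   x(t+h) = E x(t) + M u/V * e1   with u the (constant) secretion over the
# step; E = expm(A h), M = A^{-1}(E - I), computed through the real
# eigendecomposition of the 2x2 system matrix.
kinetics_step_operators <- function(kin, h) {
  A <- matrix(c(-(kin$k01 + kin$k21), kin$k21,
                kin$k12, -kin$k12), nrow = 2)
  eg <- eigen(A)
  Vm <- eg$vectors
  E <- Vm %*% diag(exp(eg$values * h)) %*% solve(Vm)
  M <- solve(A, E - diag(2))
  list(E = E, M = M)
}

#' Forward two-compartment C-peptide model
#'
#' Computes the plasma C-peptide concentration produced by a known insulin
#' secretion trace under two-compartment kinetics, solving the linear system
#' exactly per grid step (matrix exponential of the constant system matrix;
#' secretion held piecewise constant over each step).  The peripheral
#' compartment starts in exchange equilibrium with the initial plasma
#' concentration `c0`.
#'
#' @param isr an [isr_trace()] on a uniform grid.
#' @param kin a [cpeptide_kinetics()] object.
#' @param c0 initial plasma C-peptide concentration, pmol/l.
#' @return numeric vector of plasma C-peptide (pmol/l) at `isr$time`.
#' @examples
#' kin <- cpeptide_kinetics(0.06, 0.05, 0.05, 3.5)
#' tr <- isr_trace(0:180, rep(100, 181))
#' cp <- forward_cpeptide(tr, kin, c0 = 100 / (0.06 * 3.5))
#' @export
forward_cpeptide <- function(isr, kin, c0 = 0) {
  if (!inherits(isr, "isr_trace")) stop("'isr' must be an isr_trace")
  if (!inherits(kin, "cpeptide_kinetics")) {
    stop("'kin' must be a cpeptide_kinetics object")
  }
  check_nonnegative(c0, "c0")
  h <- isr$time[2] - isr$time[1]
  op <- kinetics_step_operators(kin, h)
  n <- length(isr$time)
  out <- numeric(n)
  # peripheral pseudo-concentration in exchange equilibrium with plasma
  x <- c(c0, kin$k21 / kin$k12 * c0)
  out[1] <- c0
  for (i in seq_len(n - 1)) {
    x <- op$E %*% x + op$M %*% c(isr$isr[i] / kin$V, 0)
    out[i + 1] <- x[1]
  }
  out
}
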