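# Independent oracles used across the test files.  These deliberately avoid
# the package's own code paths: the ODE oracle integrates the compartment
# system with an adaptive stiff solver, and the combinatorial oracles
# enumerate by brute force.

# adaptive-solver solution of the two-compartment C-peptide system for an
# arbitrary secretion function of time (pmol/min)
ode_cpeptide_oracle <- function(isr_fun, kin, c0, times) {
  rhs <- function(t, y, parms) {
    with(as.list(parms), {
      dc1 <- -(k01 + k21) * y[1] + k12 * y[2] + isr_fun(t) / V
      dc2 <- k21 * y[1] - k12 * y[2]
      list(c(dc1, dc2))
    })
  }
  y0 <- c(c0, kin$k21 / kin$k12 * c0)
  out <- deSolve::lsoda(y0, times, rhs,
                        parms = c(k01 = kin$k01, k12 = kin$k12,
                                  k21 = kin$k21, V = kin$V),
                        rtol = 1e-10, atol = 1e-10)
  out[, 2]
}

# exact two-sided Mann-Whitney p by enumerating all group assignments of the
# pooled sample (no ties assumed)
mw_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# exact two-sided Fisher p for a 2x2 table by hypergeometric enumeration
fisher_exact_oracle <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided Spearman permutation p by lexicographic enumeration of all
# orderings (iterative next-permutation, so it shares no code with the
# package's recursive generator)
spearman_exact_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  n <- length(y)
  a <- seq_len(n)
  rhos <- numeric(factorial(n))
  idx <- 1L
  repeat {
    rhos[idx] <- stats::cor(rx, ry[a])
    # find the rightmost ascent
    i <- n - 1L
    while (i >= 1L && a[i] >= a[i + 1L]) i <- i - 1L
    if (i < 1L) break
    j <- n
    while (a[j] <= a[i]) j <- j - 1L
    tmp <- a[i]; a[i] <- a[j]; a[j] <- tmp
    a[(i + 1L):n] <- rev(a[(i + 1L):n])
    idx <- idx + 1L
  }
  stopifnot(idx == factorial(n))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# per-sample counting oracle for CGM range percentages on a gap-free,
# uniformly sampled trace
cgm_counting_oracle <- function(glucose) {
  n <- length(glucose)
  list(
    tbr = sum(glucose < 3.9) / n * 100,
    tir = sum(glucose >= 3.9 & glucose <= 10) / n * 100,
    tar = sum(glucose > 10) / n * 100,
    above78 = sum(glucose > 7.8) / n * 100,
    above67 = sum(glucose > 6.7) / n * 100
  )
}

# a smooth reference MMTT setting shared by recovery tests
reference_betacell_setup <- function() {
  tt <- 0:180
  G <- 7.2 + 2.8 * (tt / 45) * exp(1 - tt / 45)
  dG <- c(diff(G), 0)
  params <- beta_cell_params(110, 130, 500,
                             potentiation = linear_potentiation(1.6))
  list(time = tt, glucose = G, dgdt = dG, params = params,
       isr = model_isr(params, tt, G, dG))
}
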