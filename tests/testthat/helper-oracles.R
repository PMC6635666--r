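# Shared fixtures and independent oracles for the test suite.
# The bundled reference parameter set is rebuilt explicitly here (not via
# macro_params() defaults) so that tests do not silently follow a changed
# default.

reference_params <- function(B = 0, N0 = 5) {
  macro_params(l_F = 1, l_S = 1, a_F = 1, a_S = 0.5,
               c_F0 = 1, c_S0 = 0.5, e_F = 1, e_S = 1,
               m_F = 0.01, m_S = 0.1, B = B, N0 = N0, F0 = 1, S0 = 1)
}

# randomized perturbations within a factor of 4 of the reference rates
perturbed_params <- function(n, seed = 1) {
  set.seed(seed)
  base <- unclass(reference_params())
  rate_keys <- c("l_F", "l_S", "a_F", "a_S", "c_F0", "c_S0",
                 "e_F", "e_S", "m_F", "m_S", "N0")
  lapply(seq_len(n), function(i) {
    p <- base
    for (k in rate_keys) p[[k]] <- p[[k]] * 4^stats::runif(1, -1, 1)
    p$B <- if (i %% 2 == 0) 0 else stats::runif(1, 0, 2)
    as_macro_params(p)
  })
}

# independent 1-D bisection oracle for the submerged-only equilibrium:
# solves the per-capita condition -l_S + a_S N - c_S0 exp(-e_S N) S = 0
# with N = N0 + m_F F0 - m_S (S - S0), by plain interval halving
bisect_submerged_only <- function(p, lo = 1e-9, hi = NULL, iters = 200) {
  if (is.null(hi)) hi <- (p$N0 + p$m_F * p$F0 + p$m_S * p$S0) / p$m_S
  g <- function(S) {
    N <- p$N0 - p$m_F * (0 - p$F0) - p$m_S * (S - p$S0)
    -p$l_S + p$a_S * N - p$c_S0 * exp(-p$e_S * N) * S
  }
  if (g(lo) * g(hi) > 0) return(NA_real_)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (g(lo) * g(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# central finite-difference Jacobian of the rhs (independent of the
# analytic macro_jacobian)
fd_jacobian <- function(Fv, Sv, p, h = NULL) {
  if (is.null(h)) h <- 1e-6 * max(1, abs(Fv), abs(Sv))
  rF <- function(f, s) macro_rhs(f, s, p)$dF
  rS <- function(f, s) macro_rhs(f, s, p)$dS
  matrix(c((rF(Fv + h, Sv) - rF(Fv - h, Sv)) / (2 * h),
           (rS(Fv + h, Sv) - rS(Fv - h, Sv)) / (2 * h),
           (rF(Fv, Sv + h) - rF(Fv, Sv - h)) / (2 * h),
           (rS(Fv, Sv + h) - rS(Fv, Sv - h)) / (2 * h)), nrow = 2L)
}

# conserved quantity along a trajectory
conserved_quantity <- function(traj, p) {
  p$m_F * traj$F + p$m_S * traj$S + traj$N
}

expect_conservation <- function(traj, p, tol = 1e-12) {
  q <- conserved_quantity(traj, p)
  q0 <- p$m_F * p$F0 + p$m_S * p$S0 + p$N0
  expect_lt(max(abs(q - q0)) / abs(q0), tol)
}
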