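test_that("the trivial equilibrium is always present and classified exactly", {
  for (p in c(list(reference_params(), reference_params(B = 3)),
              perturbed_params(5, seed = 4))) {
    eqs <- find_equilibria(p)
    kinds <- vapply(eqs, `[[`, character(1), "kind")
    expect_true("trivial" %in% kinds)
    triv <- eqs[[which(kinds == "trivial")]]
    # at (0,0) the Jacobian is diagonal: the F eigenvalue is exactly
    # -l_F + a_F N(0,0) - B, the S eigenvalue -l_S + a_S N(0,0)
    N00 <- nutrient_level(0, 0, p)
    lam <- sort(Re(triv$eigenvalues))
    expect_equal(lam, sort(c(-p$l_F + p$a_F * N00 - p$B,
                             -p$l_S + p$a_S * N00)), tolerance = 1e-12)
    if (p$a_F * N00 > p$l_F + p$B) {
      expect_identical(triv$stability, "unstable")  # floating invades
    }
  }
})

test_that("submerged-only equilibrium matches an independent bisection oracle", {
  p <- reference_params()
  S_oracle <- bisect_submerged_only(p)
  eqs <- find_equilibria(p)
  sub <- Filter(function(e) e$kind == "submerged_only", eqs)
  expect_length(sub, 1L)
  expect_equal(sub[[1]]$S_star, S_oracle, tolerance = 1e-9)
  expect_equal(sub[[1]]$N_star,
               nutrient_level(0, S_oracle, p), tolerance = 1e-9)
  # residuals meet the fixed-point invariant
  for (e in eqs) {
    r <- macro_rhs(e$F_star, e$S_star, p)
    expect_lt(max(abs(r$dF), abs(r$dS)), 1e-9)
  }
})

test_that("raising B beyond the invasion bound removes the floating branch", {
  p <- reference_params()
  # at F -> 0+ the floating per-capita rate is a_F N(0,0) - l_F - B;
  # push B above it and no positive floating-only root can survive
  p$B <- p$a_F * nutrient_level(0, 0, p) - p$l_F + 0.5
  eqs <- find_equilibria(p)
  kinds <- vapply(eqs, `[[`, character(1), "kind")
  expect_false("floating_only" %in% kinds)
  expect_false("coexistence" %in% kinds)
})

test_that("stability classification is consistent with simulation endpoints", {
  for (B in c(0, 2.2)) {
    p <- reference_params(B = B)
    tr <- simulate_macro(p)
    n <- nrow(tr)
    eqs <- find_equilibria(p)
    d <- vapply(eqs, function(e) {
      sqrt((e$F_star - tr$F[n])^2 + (e$S_star - tr$S[n])^2)
    }, numeric(1))
    nearest <- eqs[[which.min(d)]]
    expect_lt(min(d), 1e-6)
    expect_identical(nearest$stability, "stable")
    expect_true(all(Re(nearest$eigenvalues) < 0))
  }
})

test_that("root-finder and grid oracle agree one-to-one on the reference set", {
  p <- reference_params()
  eqs <- find_equilibria(p)
  hits <- grid_oracle(p)
  cell <- sqrt(attr(hits, "cell_F")^2 + attr(hits, "cell_S")^2)
  expect_identical(length(eqs), nrow(hits))
  for (e in eqs) {
    d <- sqrt((hits$F - e$F_star)^2 + (hits$S - e$S_star)^2)
    expect_lt(min(d), cell)
  }
  for (i in seq_len(nrow(hits))) {
    d <- vapply(eqs, function(e) {
      sqrt((hits$F[i] - e$F_star)^2 + (hits$S[i] - e$S_star)^2)
    }, numeric(1))
    expect_lt(min(d), cell)
  }
})

test_that("vanishing self-limitation leaves only the origin in a bounded box", {
  # with c0 -> 0 and no nutrient feedback, growth is unbounded and the
  # norm surface has no interior minima: the oracle sees only the origin
  p <- macro_params(l_F = 1, l_S = 1, a_F = 1, a_S = 0.5,
                    c_F0 = 1e-10, c_S0 = 1e-10, e_F = 0, e_S = 0,
                    m_F = 0, m_S = 0, B = 0, N0 = 5, F0 = 1, S0 = 1)
  hits <- grid_oracle(p, F_max = 50, S_max = 50, resolution = 60)
  expect_identical(nrow(hits), 1L)
  expect_equal(hits$F[1], 0)
  expect_equal(hits$S[1], 0)
})

test_that("analytic Jacobians at every found equilibrium match differences", {
  for (p in c(list(reference_params()), perturbed_params(4, seed = 5))) {
    for (e in find_equilibria(p)) {
      J <- unname(macro_jacobian(e$F_star, e$S_star, p))
      Jfd <- fd_jacobian(e$F_star, e$S_star, p)
      expect_equal(J, Jfd, tolerance = 1e-6)
    }
  }
})
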