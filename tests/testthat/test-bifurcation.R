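test_that("scan over B locates a single dominance flip with valid bracketing", {
  p <- reference_params()
  sc <- scan_B(p, c(0, 0.6, 1.2, 1.8), refine_width = 1e-3)
  expect_identical(sc$results$outcome,
                   c("floating_dominant", "floating_dominant",
                     "submerged_dominant", "submerged_dominant"))
  expect_length(sc$B_star, 1L)
  # the refined threshold lies between the flanking grid points
  expect_gt(sc$B_star, 0.6)
  expect_lt(sc$B_star, 1.2)
  # consistency triangle at a sub- and a super-critical B: scan outcome,
  # long-run endpoint, and the stable equilibrium set must agree
  for (i in c(1L, 4L)) {
    eqs <- find_equilibria(macro_params(B = sc$results$B[i]))
    stable <- Filter(function(e) e$stability == "stable", eqs)
    expect_length(stable, 1L)
    dom_eq <- if (stable[[1]]$F_star > stable[[1]]$S_star) {
      "floating_dominant"
    } else {
      "submerged_dominant"
    }
    expect_identical(dom_eq, sc$results$outcome[i])
    expect_identical(sc$results$stable_kinds[i], stable[[1]]$kind)
  }
  # degenerate grid: a single point, no threshold
  sc0 <- scan_B(p, 0)
  expect_length(sc0$B_star, 0L)
  expect_identical(sc0$results$outcome, "floating_dominant")
})

test_that("both critical rates are located and ordered as the model demands", {
  p <- reference_params()
  cb <- critical_biocontrol(p, refine_width = 1e-4)
  # the exclusion threshold equals a_F N*_S - l_F at the submerged-only
  # state found by the independent bisection oracle
  S_star <- bisect_submerged_only(p)
  expect_equal(cb$exclusion, p$a_F * nutrient_level(0, S_star, p) - p$l_F,
               tolerance = 1e-9)
  # the dominance flip sits below the exclusion point: there is a window
  # of B where the submerged plant dominates but the floating persists
  expect_lt(cb$dominance, cb$exclusion)
  # simulated outcomes straddle the dominance threshold
  lo <- reference_params(B = cb$dominance - 0.05)
  hi <- reference_params(B = cb$dominance + 0.05)
  trl <- simulate_macro(lo)
  trh <- simulate_macro(hi)
  expect_gt(trl$F[nrow(trl)], trl$S[nrow(trl)])
  expect_lt(trh$F[nrow(trh)], trh$S[nrow(trh)])
})

test_that("required biocontrol for the complete switch grows with nutrients", {
  p <- reference_params()
  sweep <- critical_B_vs_N0(p, c(2.5, 3.5, 5))
  expect_identical(sweep$status, rep("ok", 3L))
  expect_true(all(diff(sweep$B_exclusion) > 0))
  # the dominance flip is flat in N0 here: a coincidence of the reference
  # rates (a_F c_S0 = a_S c_F0 with equal e), detected, not assumed
  expect_true(all(abs(sweep$B_dominance - sweep$B_dominance[1]) < 5e-3))
})

test_that("when the floating plant cannot establish the threshold degenerates", {
  # uptake so weak that a_F N(0,0) < l_F: floating cannot invade even at
  # B = 0, while the submerged plant still establishes
  p <- reference_params()
  p$a_F <- 0.15
  p <- as_macro_params(unclass(p))
  cb <- critical_biocontrol(p)
  expect_identical(cb$dominance, 0)
  expect_identical(cb$exclusion, 0)
  sc <- scan_B(p, c(0, 0.5, 1))
  expect_identical(unique(sc$results$outcome), "submerged_dominant")
  expect_length(sc$B_star, 0L)
})

test_that("bistability probe verdicts and symmetry", {
  # reference regime at B = 0: a single interior attractor
  bp <- bistability_probe(reference_params(), B = 0, n_starts = 9)
  expect_identical(bp$verdict, "monostable")
  expect_identical(nrow(bp$attractors), 1L)
  eqs <- find_equilibria(reference_params())
  stable <- Filter(function(e) e$stability == "stable", eqs)
  expect_equal(bp$attractors$F[1], stable[[1]]$F_star, tolerance = 1e-5)
  # fully symmetric parameters: endpoints mirror under F <-> S exchange
  psym <- macro_params(l_F = 1, l_S = 1, a_F = 0.7, a_S = 0.7,
                       c_F0 = 0.8, c_S0 = 0.8, e_F = 1, e_S = 1,
                       m_F = 0.05, m_S = 0.05, B = 0,
                       N0 = 4, F0 = 1, S0 = 1)
  bps <- bistability_probe(psym, B = 0, n_starts = 9)
  ep <- bps$endpoints
  for (i in seq_len(nrow(ep))) {
    j <- which(abs(ep$F_start - ep$S_start[i]) < 1e-12 &
                 abs(ep$S_start - ep$F_start[i]) < 1e-12)
    expect_true(length(j) >= 1L)
    expect_equal(ep$F_end[i], ep$S_end[j[1]], tolerance = 1e-6)
    expect_equal(ep$S_end[i], ep$F_end[j[1]], tolerance = 1e-6)
  }
})
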