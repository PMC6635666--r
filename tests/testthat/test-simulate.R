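test_that("empty system stays empty and trajectories satisfy invariants", {
  p <- reference_params()
  p$F0 <- 0
  p$S0 <- 0
  tr <- simulate_macro(p, t_end = 10, steady_stop = FALSE, n_samples = 50)
  expect_true(all(tr$F == 0))
  expect_true(all(tr$S == 0))

  for (pp in list(reference_params(), reference_params(B = 2.2),
                  reference_params(B = 0.5, N0 = 2.5))) {
    for (m in c("adaptive", "euler")) {
      tr <- simulate_macro(pp, t_end = 60, method = m, n_samples = 400)
      expect_true(all(diff(tr$t) > 0))
      expect_true(all(tr$F >= 0 & tr$S >= 0))
      expect_conservation(tr, pp)
    }
  }
})

test_that("endpoint without biocontrol is the stable floating-dominant state", {
  p <- reference_params()
  tr <- simulate_macro(p)
  n <- nrow(tr)
  expect_gt(tr$F[n], tr$S[n])  # floating dominance plateau
  # growth is initially positive
  expect_gt(tr$F[2], tr$F[1])
  # endpoint agrees with the stable equilibrium from the root-finder
  eqs <- find_equilibria(p)
  stable <- Filter(function(e) e$stability == "stable", eqs)
  expect_length(stable, 1L)
  d <- sqrt((stable[[1]]$F_star - tr$F[n])^2 + (stable[[1]]$S_star - tr$S[n])^2)
  expect_lt(d, 1e-6)
})

test_that("strong biocontrol drives monotone floating decline to extinction", {
  # a_F N <= l_F + B along the whole trajectory forces decline
  p <- reference_params(B = 6)
  tr <- simulate_macro(p)
  expect_true(all(diff(tr$F) <= 0))
  expect_true(attr(tr, "extinct")["F"])
  expect_lt(tr$F[nrow(tr)], 1e-9)
})

test_that("switch detection finds, refines, and flags degenerate cases", {
  p <- reference_params(B = 2.2)
  tr <- simulate_macro(p)
  sw <- detect_switch(tr)
  expect_identical(sw$status, "switch")
  expect_true(is.finite(sw$t_switch))
  # S <= F at every sample strictly before the crossing
  before <- tr$t < sw$t_switch
  expect_true(all(tr$S[before] <= tr$F[before]))
  # no switch without biocontrol: floating dominance is maintained
  expect_identical(detect_switch(simulate_macro(reference_params()))$status,
                   "none")
  # exact ties are never a switch
  tie <- simulate_macro(macro_params(l_F = 1, l_S = 1, a_F = 1, a_S = 1,
                                     c_F0 = 1, c_S0 = 1, e_F = 1, e_S = 1,
                                     m_F = 0.1, m_S = 0.1, B = 0,
                                     N0 = 5, F0 = 1, S0 = 1),
                        t_end = 20, n_samples = 100,
                        method = "euler", dt = 0.05)
  expect_identical(detect_switch(tie)$status, "tie")
  # an already-inverted start is reported distinctly, not as an event
  pinv <- reference_params()
  pinv$S0 <- 2
  expect_identical(detect_switch(simulate_macro(pinv, t_end = 10,
                                                n_samples = 50))$status,
                   "inverted_start")
})

test_that("switch time is non-increasing in the biocontrol rate", {
  p <- reference_params()
  curve <- time_to_switch_curve(p, c(0, 0.5, 1.2, 1.5, 1.8, 2.1, 2.4))
  expect_identical(curve$status[1:2], c("none", "none"))
  ts <- curve$t_switch[curve$status == "switch"]
  expect_length(ts, 5L)
  expect_true(all(diff(ts) <= 1e-9))
})

test_that("fixed-step Euler converges to the adaptive solution at first order", {
  p <- reference_params()
  t_end <- 20
  n <- 200
  ref <- simulate_macro(p, t_end = t_end, n_samples = n, rtol = 1e-10,
                        atol = 1e-12, steady_stop = FALSE)
  err <- vapply(c(0.01, 0.005), function(dt) {
    eu <- simulate_macro(p, t_end = t_end, method = "euler", dt = dt,
                         n_samples = n, steady_stop = FALSE)
    max(abs(eu$F - ref$F) + abs(eu$S - ref$S))
  }, numeric(1))
  expect_lt(err[2], err[1])           # converging toward the reference
  expect_gt(err[1] / err[2], 1.7)     # ~first-order: halving dt halves error
  expect_lt(err[1] / err[2], 2.3)
})

test_that("steady-state early stop truncates the quiescent tail", {
  tr <- simulate_macro(reference_params())
  expect_identical(attr(tr, "termination"), "steady_state")
  expect_lt(tr$t[nrow(tr)], 200)
  r <- macro_rhs(tr$F[nrow(tr)], tr$S[nrow(tr)], reference_params())
  expect_lt(max(abs(r$dF), abs(r$dS)), 1e-10)
  tr2 <- simulate_macro(reference_params(), steady_stop = FALSE)
  expect_identical(attr(tr2, "termination"), "t_end")
  expect_equal(tr2$t[nrow(tr2)], 200)
})

test_that("trajectory export is deterministic and round-trips numerically", {
  p <- reference_params(B = 2.2)
  tr <- simulate_macro(p, t_end = 30, n_samples = 100)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_trajectory(tr, f1)
  write_trajectory(simulate_macro(p, t_end = 30, n_samples = 100), f2)
  expect_identical(readLines(f1), readLines(f2))  # bit-identical reruns
  back <- utils::read.csv(f1)
  expect_equal(back$F, tr$F, tolerance = 1e-11)
  meta <- yaml::read_yaml(paste0(tools::file_path_sans_ext(f1), ".meta.yaml"))
  expect_identical(meta$method, "adaptive")
  expect_equal(meta$params$B, 2.2)
  expect_identical(meta$switch$status, "switch")
})
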