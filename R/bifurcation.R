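# Steady-state endpoint of a simulation, with the dominance verdict.
# Dominance is operationalised as the larger biomass at the steady-state
# endpoint; exact and near ties (within tie_tol relative) are flagged.
steady_outcome <- function(params, tie_tol = 1e-8, ...) {
  traj <- withCallingHandlers(
    simulate_macro(params, ...),
    warning = function(w) invokeRestart("muffleWarning"))
  n <- nrow(traj)
  Fe <- traj$F[n]; Se <- traj$S[n]
  outcome <- if (abs(Fe - Se) <= tie_tol * (1 + max(Fe, Se))) "tie"
             else if (Fe > Se) "floating_dominant"
             else "submerged_dominant"
  sw <- detect_switch(traj)
  list(outcome = outcome, F_end = Fe, S_end = Se,
       t_switch = sw$t_switch, switch_status = sw$status,
       converged = identical(attr(traj, "termination"), "steady_state"),
       floating_extinct = unname(attr(traj, "extinct")["F"]))
}

#' Scan the biocontrol rate for the dominance threshold
#'
#' For each value of the biocontrol rate `B` on the grid, simulates the
#' model to steady state from `(F0, S0)` and records which species
#' dominates the endpoint (larger steady biomass), the switch time, and
#' which stable equilibria are present.  Wherever two adjacent grid points
#' have differing dominance outcomes, the critical rate is refined by
#' bisection on the outcome until the bracket width falls below
#' `refine_width` times the grid span.
#'
#' Note that this model has a second, distinct critical rate -- the
#' floating-exclusion threshold at which the floating plant can no longer
#' persist at all; see [critical_biocontrol()].
#'
#' @param params a [macro_params()] object; `B` is overridden by the grid.
#' @param B_grid strictly increasing, non-negative biocontrol rates.
#' @param refine_width bisection target width, as a fraction of the span.
#' @param ... passed to [simulate_macro()].
#' @return An object of class `macro_scan`: a list with `results` (a data
#'   frame: `B`, `outcome`, `F_end`, `S_end`, `t_switch`, `converged`,
#'   `stable_kinds`), `B_star` (numeric vector of refined dominance
#'   thresholds; length 0 when the outcome never flips), `param = "B"`
#'   and the grid.
#' @export
scan_B <- function(params, B_grid, refine_width = 1e-4, ...) {
  params <- as_macro_params(params)
  stopifnot(length(B_grid) > 0L, all(B_grid >= 0),
            !is.unsorted(B_grid, strictly = length(B_grid) > 1L))
  at_B <- function(b) { p <- params; p$B <- b; p }
  rows <- lapply(B_grid, function(b) {
    o <- tryCatch(steady_outcome(at_B(b), ...), error = function(e) NULL)
    stable <- tryCatch({
      eqs <- find_equilibria(at_B(b))
      kinds <- vapply(eqs, `[[`, character(1L), "kind")
      st <- vapply(eqs, `[[`, character(1L), "stability")
      paste(sort(kinds[st == "stable"]), collapse = "+")
    }, error = function(e) NA_character_)
    if (is.null(o)) {
      return(data.frame(B = b, outcome = "error", F_end = NA_real_,
                        S_end = NA_real_, t_switch = NA_real_,
                        converged = FALSE, stable_kinds = stable))
    }
    if (!o$converged) {
      warning(sprintf("simulation at B = %g did not reach steady state; ",
                      b), "excluded from threshold refinement",
              call. = FALSE)
    }
    data.frame(B = b, outcome = o$outcome, F_end = o$F_end,
               S_end = o$S_end, t_switch = o$t_switch,
               converged = o$converged, stable_kinds = stable)
  })
  results <- do.call(rbind, rows)
  span <- max(diff(range(B_grid)), .Machine$double.eps)
  usable <- results$outcome %in% c("floating_dominant", "submerged_dominant") &
    results$converged
  B_star <- numeric(0)
  idx <- which(usable)
  if (length(idx) >= 2L) {
    for (k in seq_len(length(idx) - 1L)) {
      i <- idx[k]; j <- idx[k + 1L]
      if (results$outcome[i] != results$outcome[j]) {
        B_star <- c(B_star, bisect_outcome(
          function(b) steady_outcome(at_B(b), ...)$outcome,
          results$B[i], results$B[j],
          results$outcome[i], results$outcome[j],
          width = refine_width * span))
      }
    }
  }
  structure(list(results = results, B_star = B_star, param = "B",
                 grid = B_grid), class = "macro_scan")
}

# bisection on a categorical outcome; the bracket endpoints always carry
# differing outcomes, and the interval width shrinks monotonically
bisect_outcome <- function(outcome_fn, lo, hi, out_lo, out_hi, width) {
  while (hi - lo > width) {
    mid <- (lo + hi) / 2
    om <- outcome_fn(mid)
    if (om == out_lo || om == "tie") {
      lo <- mid
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

#' @export
print.macro_scan <- function(x, ...) {
  cat(sprintf("<macro_scan> over %s, %d grid points\n", x$param,
              nrow(x$results)))
  print(x$results, row.names = FALSE)
  if (length(x$B_star) > 0L) {
    cat("  dominance threshold(s):",
        paste(format(x$B_star, digits = 6), collapse = ", "), "\n")
  } else {
    cat("  no dominance flip on the grid\n")
  }
  invisible(x)
}

#' Critical biocontrol thresholds
#'
#' This model has two distinct critical biocontrol rates, and the package
#' computes both:
#'
#' * `dominance`: the rate at which long-run dominance (the larger
#'   steady-state biomass reached from `(F0, S0)`) flips from floating to
#'   submerged.  Located by bisection on the simulated outcome.  At the
#'   bundled parameter values this threshold is degenerate in an
#'   instructive way: because `a_F c_S0 = a_S c_F0` and `e_F = e_S`, the
#'   biomass gap at the interior equilibrium is
#'   `F* - S* = (1 - B) exp(N*)` (in the bundled units), so the flip sits
#'   at `B = 1` independent of nutrient loading.
#' * `exclusion`: the rate beyond which the floating plant cannot persist
#'   at all and the switch is complete.  This is the transcritical point
#'   where the floating invasion rate at the submerged-only equilibrium,
#'   `a_F N*_S - l_F - B`, changes sign; since the submerged equation does
#'   not involve `B`, it is obtained in closed form as
#'   `B_excl = a_F N*_S - l_F`.  Unlike the dominance flip, this
#'   threshold increases with nutrient loading, which is the model's
#'   headline interaction of bottom-up and top-down drivers.
#'
#' @param params a [macro_params()] object (its `B` entry is ignored).
#' @param refine_width bisection target width for the dominance
#'   threshold, as a fraction of the search span.
#' @param B_max upper limit of the dominance bracket search; default
#'   grows from `max(1, exclusion)` by doubling.
#' @param ... passed to [simulate_macro()].
#' @return A list with components `dominance` and `exclusion` (each a
#'   single rate, `NA` when degenerate/absent), plus `details` (the
#'   submerged-only equilibrium used, and degeneracy notes).
#' @export
critical_biocontrol <- function(params, refine_width = 1e-4, B_max = NULL,
                                ...) {
  params <- as_macro_params(params)
  note <- character(0)

  # exclusion threshold from the submerged-only branch (B-independent)
  eqs <- find_equilibria(params)
  kinds <- vapply(eqs, `[[`, character(1L), "kind")
  sub <- eqs[kinds == "submerged_only"]
  # keep branch-stable roots (attracting within the S axis)
  sub <- Filter(function(e) {
    macro_jacobian(0, e$S_star, params)[2L, 2L] < 0
  }, sub)
  if (length(sub) == 0L) {
    exclusion <- NA_real_
    note <- c(note, "no attracting submerged-only equilibrium")
    sub_eq <- NULL
  } else {
    sub_eq <- sub[[which.max(vapply(sub, `[[`, numeric(1L), "S_star"))]]
    exclusion <- params$a_F * sub_eq$N_star - params$l_F
    if (exclusion <= 0) {
      note <- c(note,
                "floating plant cannot invade even without biocontrol")
      exclusion <- 0
    }
  }

  # dominance threshold by bisection on the simulated outcome
  at_B <- function(b) { p <- params; p$B <- b; p }
  out0 <- steady_outcome(at_B(0), ...)$outcome
  if (out0 != "floating_dominant") {
    dominance <- if (out0 == "submerged_dominant") 0 else NA_real_
    note <- c(note, sprintf("outcome at B = 0 is %s", out0))
  } else {
    hi <- B_max
    if (is.null(hi)) hi <- max(1, if (is.finite(exclusion)) exclusion else 1)
    out_hi <- steady_outcome(at_B(hi), ...)$outcome
    tries <- 0L
    while (out_hi != "submerged_dominant" && tries < 12L) {
      hi <- hi * 2
      out_hi <- steady_outcome(at_B(hi), ...)$outcome
      tries <- tries + 1L
    }
    if (out_hi != "submerged_dominant") {
      dominance <- NA_real_
      note <- c(note, "no submerged-dominant outcome found up to B_max")
    } else {
      dominance <- bisect_outcome(
        function(b) steady_outcome(at_B(b), ...)$outcome,
        0, hi, out0, out_hi, width = refine_width * hi)
    }
  }
  list(dominance = dominance, exclusion = exclusion,
       details = list(submerged_only = sub_eq, notes = note))
}

#' Critical biocontrol rate as a function of nutrient loading
#'
#' Computes both critical rates of [critical_biocontrol()] for each
#' initial nutrient level.  Across the regime around the bundled
#' parameters the exclusion threshold is non-decreasing in `N0`: richer
#' water demands more biocontrol pressure for the complete switch, i.e.
#' the required control is reduced in lower-nutrient settings.  Per-level
#' failures are recorded without aborting the sweep.
#'
#' @param params a [macro_params()] object; `N0` is overridden.
#' @param N0_values non-empty, positive nutrient levels.
#' @param ... passed to [critical_biocontrol()].
#' @return A data frame with columns `N0`, `B_dominance`, `B_exclusion`,
#'   `status`.
#' @export
critical_B_vs_N0 <- function(params, N0_values, ...) {
  params <- as_macro_params(params)
  stopifnot(length(N0_values) > 0L, all(N0_values > 0))
  rows <- lapply(N0_values, function(n0) {
    p <- params
    p$N0 <- n0
    tryCatch({
      cb <- critical_biocontrol(p, ...)
      data.frame(N0 = n0, B_dominance = cb$dominance,
                 B_exclusion = cb$exclusion, status = "ok")
    }, error = function(e) {
      data.frame(N0 = n0, B_dominance = NA_real_, B_exclusion = NA_real_,
                 status = paste("error:", conditionMessage(e)))
    })
  })
  do.call(rbind, rows)
}

#' Probe for bistability at fixed parameters
#'
#' Simulates the model from a deterministic lattice of initial states
#' inside the conservation simplex (total nutrient stock held fixed by
#' adjusting `N0` so that every start lives on the same vector field),
#' clusters the steady endpoints, and reports `"bistable"` when two or
#' more distinct attractors are found beyond `tol`.  Whether the printed
#' parameter regime is truly bistable at fixed `B` or has a single
#' attractor that moves with `B` is a finding of this probe, not an
#' assumption of the package.
#'
#' @param params a [macro_params()] object.
#' @param B biocontrol rate at which to probe.
#' @param n_starts requested number of lattice starts (>= 2; rounded up
#'   to a square, plus the nominal start `(F0, S0)`).
#' @param tol endpoint clustering tolerance in `(F, S)`.
#' @param ... passed to [simulate_macro()].
#' @return A list with `verdict` (`"monostable"` or `"bistable"`),
#'   `attractors` (data frame `F`, `S`, `N`, `n_basin`), and `endpoints`
#'   (one row per start).
#' @export
bistability_probe <- function(params, B = params$B, n_starts = 25,
                              tol = 1e-4, ...) {
  params <- as_macro_params(params)
  stopifnot(n_starts >= 2)
  params$B <- B
  total <- nutrient_total(params)
  k <- ceiling(sqrt(n_starts))
  scale_axis <- function(bound) bound * 10^seq(-4, log10(0.8),
                                               length.out = k)
  starts <- rbind(expand.grid(F = scale_axis(biomass_bound(params, "F")),
                              S = scale_axis(biomass_bound(params, "S"))),
                  data.frame(F = params$F0, S = params$S0))
  # keep starts inside the conservation simplex (non-negative nutrients)
  ok <- total - params$m_F * starts$F - params$m_S * starts$S >= 0
  starts <- starts[ok, , drop = FALSE]
  rows <- lapply(seq_len(nrow(starts)), function(i) {
    p <- params
    p$F0 <- starts$F[i]
    p$S0 <- starts$S[i]
    p$N0 <- total - params$m_F * p$F0 - params$m_S * p$S0  # same field
    o <- tryCatch(steady_outcome(p, ...), error = function(e) NULL)
    if (is.null(o)) return(NULL)
    data.frame(F_start = p$F0, S_start = p$S0, F_end = o$F_end,
               S_end = o$S_end, converged = o$converged)
  })
  endpoints <- do.call(rbind, rows)
  conv <- endpoints[endpoints$converged, , drop = FALSE]
  reps <- list()
  counts <- integer(0)
  for (i in seq_len(nrow(conv))) {
    pt <- c(conv$F_end[i], conv$S_end[i])
    hit <- which(vapply(reps, function(r) {
      sqrt(sum((r - pt)^2)) <= tol
    }, logical(1L)))
    if (length(hit) > 0L) {
      counts[hit[1L]] <- counts[hit[1L]] + 1L
    } else {
      reps <- c(reps, list(pt))
      counts <- c(counts, 1L)
    }
  }
  attractors <- if (length(reps) > 0L) {
    data.frame(F = vapply(reps, `[`, numeric(1L), 1L),
               S = vapply(reps, `[`, numeric(1L), 2L),
               N = vapply(reps, function(r) {
                 total - params$m_F * r[1L] - params$m_S * r[2L]
               }, numeric(1L)),
               n_basin = counts)
  } else {
    data.frame(F = numeric(0), S = numeric(0), N = numeric(0),
               n_basin = integer(0))
  }
  list(verdict = if (nrow(attractors) >= 2L) "bistable" else "monostable",
       attractors = attractors, endpoints = endpoints)
}
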