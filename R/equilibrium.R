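#' Locate all fixed points of the model
#'
#' Finds the equilibria of the competition model within the
#' parameter-derived search box `F <= (N0 + m_F F0 + m_S S0) / m_F`,
#' `S <= (N0 + m_F F0 + m_S S0) / m_S`.  The box provably contains every
#' equilibrium with positive biomass: the per-capita conditions require
#' `a_X N > 0` there, so the conservation identity caps each biomass at
#' the level that would exhaust the total nutrient stock single-handedly.
#' The branches searched are:
#'
#' * the trivial equilibrium `(0, 0)`, always present because both
#'   equations are multiplicative in the species' own biomass;
#' * floating-only roots of the per-capita condition
#'   `-l_F - B + a_F N - c_F(N) F = 0` with `N = nutrient_level(F, 0)`;
#' * submerged-only roots of `-l_S + a_S N - c_S(N) S = 0` with
#'   `N = nutrient_level(0, S)`;
#' * coexistence roots of the simultaneous per-capita conditions.  These
#'   invert in closed form to `F(N) = (a_F N - l_F - B) / c_F(N)` and
#'   `S(N) = (a_S N - l_S) / c_S(N)`, reducing the 2-D problem to a single
#'   scalar equation in `N` (the nutrient closure), which is solved by a
#'   dense sign-change scan plus bracketed root refinement -- no roots can
#'   be missed inside the scanned interval.
#'
#' All roots are polished by Newton iteration with the analytic Jacobian,
#' deduplicated (pairwise distance below `dedupe_tol`), checked against a
#' residual tolerance, classified for stability, and returned sorted by
#' `(F_star, S_star)`.
#'
#' @param params a [macro_params()] object.
#' @param res_tol residual tolerance: both growth rates at an accepted
#'   root must be below `res_tol` times the magnitude of the constituent
#'   terms (which reduces to an absolute `res_tol` at order-one scales).
#' @param dedupe_tol pairwise distance below which two roots are merged.
#' @param n_scan grid size of the sign-change scans per branch.
#' @return An object of class `macro_eq_set`: a list of `macro_equilibrium`
#'   objects, each with fields `F_star`, `S_star`, `N_star`, `kind`
#'   (`"trivial"`, `"floating_only"`, `"submerged_only"`,
#'   `"coexistence"`), `eigenvalues`, `stability` and `residual`.
#'   Convert with `as.data.frame()`.
#' @examples
#' eqs <- find_equilibria(macro_params())
#' as.data.frame(eqs)
#' @seealso [classify_stability()], [grid_oracle()]
#' @export
find_equilibria <- function(params, res_tol = 1e-9, dedupe_tol = 1e-6,
                            n_scan = 2000) {
  params <- as_macro_params(params)
  bound_F <- biomass_bound(params, "F")
  bound_S <- biomass_bound(params, "S")

  roots <- list(c(0, 0))  # trivial: guaranteed by the multiplicative form
  kinds <- "trivial"

  # --- boundary branches: 1-D per-capita conditions -----------------------
  pc_F <- function(F) {
    N <- nutrient_level(F, 0, params)
    params$a_F * N - params$l_F - params$B -
      competition(N, params$c_F0, params$e_F) * F
  }
  pc_S <- function(S) {
    N <- nutrient_level(0, S, params)
    params$a_S * N - params$l_S -
      competition(N, params$c_S0, params$e_S) * S
  }
  for (fr in scan_roots(pc_F, bound_F, n_scan)) {
    roots <- c(roots, list(c(fr, 0)))
    kinds <- c(kinds, "floating_only")
  }
  for (sr in scan_roots(pc_S, bound_S, n_scan)) {
    roots <- c(roots, list(c(0, sr)))
    kinds <- c(kinds, "submerged_only")
  }

  # --- coexistence branch: scalar closure equation in N -------------------
  if (params$a_F > 0 && params$a_S > 0) {
    F_of_N <- function(N) {
      (params$a_F * N - params$l_F - params$B) /
        competition(N, params$c_F0, params$e_F)
    }
    S_of_N <- function(N) {
      (params$a_S * N - params$l_S) /
        competition(N, params$c_S0, params$e_S)
    }
    psi <- function(N) {
      N - params$N0 + params$m_F * (F_of_N(N) - params$F0) +
        params$m_S * (S_of_N(N) - params$S0)
    }
    N_lo <- max((params$l_F + params$B) / params$a_F,
                params$l_S / params$a_S)   # below this a biomass is <= 0
    N_hi <- nutrient_total(params)         # N at zero total biomass
    if (N_hi > N_lo) {
      Ns <- scan_roots(psi, N_hi, n_scan, lower = N_lo)
      for (Nr in Ns) {
        Fr <- F_of_N(Nr); Sr <- S_of_N(Nr)
        if (is.finite(Fr) && is.finite(Sr) && Fr > 0 && Sr > 0) {
          roots <- c(roots, list(c(Fr, Sr)))
          kinds <- c(kinds, "coexistence")
        }
      }
    }
  }

  # --- polish, residual-check, dedupe -------------------------------------
  eqs <- list()
  for (i in seq_along(roots)) {
    y <- newton_polish(roots[[i]][1L], roots[[i]][2L], params,
                       boundary = kinds[i])
    r <- macro_rhs(y[1L], y[2L], params)
    if (max(abs(r$dF) / residual_scale_F(y[1L], y[2L], params),
            abs(r$dS) / residual_scale_S(y[1L], y[2L], params)) > res_tol) {
      next  # failed to converge to a genuine root
    }
    dup <- any(vapply(eqs, function(e) {
      sqrt((e$F_star - y[1L])^2 + (e$S_star - y[2L])^2) < dedupe_tol
    }, logical(1L)))
    if (dup) next
    eq <- structure(list(F_star = y[1L], S_star = y[2L],
                         N_star = nutrient_level(y[1L], y[2L], params),
                         kind = kinds[i],
                         residual = max(abs(r$dF), abs(r$dS))),
                    class = "macro_equilibrium")
    eqs <- c(eqs, list(classify_stability(eq, params)))
  }
  ord <- order(vapply(eqs, `[[`, numeric(1L), "F_star"),
               vapply(eqs, `[[`, numeric(1L), "S_star"))
  structure(eqs[ord], class = "macro_eq_set")
}

# dense sign-change scan over (lower, upper] followed by uniroot; the grid
# mixes log and linear spacing so roots near zero are not skipped
scan_roots <- function(fn, upper, n_scan, lower = 0) {
  if (upper <= lower) return(numeric(0))
  span <- upper - lower
  grid <- lower + sort(unique(c(span * 10^seq(-9, 0, length.out = 200),
                                seq(span / n_scan, span,
                                    length.out = n_scan))))
  vals <- vapply(grid, fn, numeric(1L))
  ok <- is.finite(vals)
  grid <- grid[ok]; vals <- vals[ok]
  if (length(grid) < 2L) return(numeric(0))
  flips <- which(vals[-1L] * vals[-length(vals)] < 0)
  out <- numeric(0)
  for (i in flips) {
    r <- tryCatch(
      stats::uniroot(fn, lower = grid[i], upper = grid[i + 1L],
                     tol = 1e-14 * max(1, grid[i + 1L]))$root,
      error = function(e) {
        stop(sprintf("root search failed to converge in bracket [%g, %g]",
                     grid[i], grid[i + 1L]), call. = FALSE)
      })
    out <- c(out, r)
  }
  # exact zeros on the grid count too
  c(out, grid[vals == 0])
}

# Newton polish with the analytic Jacobian; boundary roots are kept on
# their axis (1-D Newton on the surviving component)
newton_polish <- function(F, S, params, boundary = "coexistence",
                          iters = 10L) {
  y <- c(F, S)
  for (k in seq_len(iters)) {
    r <- macro_rhs(y[1L], y[2L], params)
    rv <- c(r$dF, r$dS)
    J <- macro_jacobian(y[1L], y[2L], params)
    step <- switch(boundary,
      trivial = c(0, 0),
      floating_only = c(if (J[1L, 1L] != 0) -rv[1L] / J[1L, 1L] else 0, 0),
      submerged_only = c(0, if (J[2L, 2L] != 0) -rv[2L] / J[2L, 2L] else 0),
      tryCatch(solve(J, -rv), error = function(e) c(0, 0)))
    if (!all(is.finite(step)) || max(abs(step)) == 0) break
    ynew <- unname(pmax(y + step, 0))
    rnew <- macro_rhs(ynew[1L], ynew[2L], params)
    if (max(abs(rnew$dF), abs(rnew$dS)) <= max(abs(rv))) y <- ynew
    if (max(abs(step)) < 1e-15 * max(1, max(abs(y)))) break
  }
  y
}

# magnitude of the terms making up each growth rate: the yardstick for
# relative residual checks (cancellation noise grows with these)
residual_scale_F <- function(F, S, params) {
  N <- nutrient_level(F, S, params)
  max(1, abs(params$l_F * F) + abs(params$a_F * N * F) +
        abs(competition(N, params$c_F0, params$e_F) * F^2) +
        abs(params$B * F))
}
residual_scale_S <- function(F, S, params) {
  N <- nutrient_level(F, S, params)
  max(1, abs(params$l_S * S) + abs(params$a_S * N * S) +
        abs(competition(N, params$c_S0, params$e_S) * S^2))
}

#' Linear stability of an equilibrium
#'
#' Builds the analytic 2x2 Jacobian of the model at the fixed point
#' (including the chain-rule contributions through the nutrient closure)
#' and classifies stability from the eigenvalue real parts: `"stable"` if
#' both are below `-tol`, `"unstable"` if any exceeds `+tol`, `"marginal"`
#' otherwise.  The marginality tolerance separates genuine bifurcation
#' points from floating-point noise.
#'
#' @param eq a `macro_equilibrium`, or any list with `F_star`/`S_star`.
#' @param params a [macro_params()] object.
#' @param tol marginality tolerance on eigenvalue real parts.
#' @return The equilibrium with `eigenvalues` (complex, sorted by
#'   decreasing real part) and `stability` fields filled in.
#' @export
classify_stability <- function(eq, params, tol = 1e-8) {
  params <- as_macro_params(params)
  J <- macro_jacobian(eq$F_star, eq$S_star, params)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  re <- Re(ev)
  eq$eigenvalues <- ev
  eq$stability <- if (all(re < -tol)) "stable"
                  else if (any(re > tol)) "unstable"
                  else "marginal"
  if (!inherits(eq, "macro_equilibrium")) class(eq) <- "macro_equilibrium"
  eq
}

#' @export
print.macro_equilibrium <- function(x, ...) {
  cat(sprintf("<equilibrium %s> F* = %g, S* = %g, N* = %g  [%s]\n",
              x$kind, x$F_star, x$S_star, x$N_star, x$stability))
  cat("  eigenvalues:", paste(format(x$eigenvalues, digits = 6),
                              collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.macro_eq_set <- function(x, ...) {
  cat(sprintf("<macro_eq_set> %d equilibria\n", length(x)))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.macro_eq_set <- function(x, ...) {
  out <- do.call(rbind, lapply(x, function(e) {
    data.frame(F_star = unname(e$F_star), S_star = unname(e$S_star),
               N_star = unname(e$N_star),
               kind = e$kind, stability = e$stability,
               re_lambda_1 = Re(e$eigenvalues[1L]),
               re_lambda_2 = Re(e$eigenvalues[2L]),
               residual = unname(e$residual))
  }))
  rownames(out) <- NULL
  out
}

#' Brute-force grid oracle for equilibria
#'
#' The definitional cross-check for [find_equilibria()], built directly
#' on the sign structure of the growth-rate field and sharing no code
#' path with the root-finder beyond the right-hand side itself:
#'
#' * the origin is always reported (both rates are exactly zero there);
#' * along each coordinate axis the surviving species' growth rate is
#'   scanned densely (`axis_resolution` points) for sign changes, each
#'   bracketed change being narrowed by interval halving on the rate
#'   itself;
#' * the interior is swept by an `(F, S)` grid; every cell whose corners
#'   show a sign change in *both* growth components is a candidate
#'   crossing of the two nullclines and is polished by a derivative-free
#'   simplex descent on the norm of the rate vector, clamped to the
#'   non-negative quadrant.
#'
#' A candidate is reported as a near-equilibrium when its refined norm
#' drops below `threshold` (scaled by the magnitude of the constituent
#' terms); hits closer than one grid cell are merged.  Every root
#' returned by [find_equilibria()] must lie within one grid cell of an
#' oracle hit and vice versa.
#'
#' @param params a [macro_params()] object.
#' @param F_max,S_max box bounds; default the parameter-derived bounds of
#'   [find_equilibria()].
#' @param resolution interior grid points per axis.
#' @param axis_resolution points of the dense 1-D axis scans.
#' @param threshold acceptance threshold on the refined (scaled) norm.
#' @return A data frame (class `macro_oracle`) with one row per hit:
#'   `F`, `S`, `norm`; attributes `cell_F`, `cell_S` give the interior
#'   cell sizes.
#' @export
grid_oracle <- function(params, F_max = NULL, S_max = NULL,
                        resolution = 120, axis_resolution = 20000,
                        threshold = 1e-3) {
  params <- as_macro_params(params)
  if (is.null(F_max)) F_max <- biomass_bound(params, "F")
  if (is.null(S_max)) S_max <- biomass_bound(params, "S")
  stopifnot(F_max > 0, S_max > 0, resolution >= 8, axis_resolution >= 100)
  norm_at <- function(Fv, Sv) {
    r <- macro_rhs(Fv, Sv, params)
    sqrt(r$dF^2 + r$dS^2)
  }
  hits <- list(data.frame(F = 0, S = 0, norm = 0))

  # --- dense axis scans: the system is one-dimensional on each axis ------
  axis_roots <- function(grid, rate_at) {
    v <- rate_at(grid)
    v[!is.finite(v)] <- NA_real_
    ok <- !is.na(v)
    g <- grid[ok]; vv <- v[ok]
    out <- g[vv == 0 & g > 0]
    flips <- which(vv[-1L] * vv[-length(vv)] < 0)
    for (i in flips) {
      lo <- g[i]; hi <- g[i + 1L]
      flo <- vv[i]
      for (it in 1:200) {          # plain interval halving on the rate
        mid <- (lo + hi) / 2
        fm <- rate_at(mid)
        if (flo * fm <= 0) hi <- mid else { lo <- mid; flo <- fm }
        if (hi - lo < 1e-13 * max(1, hi)) break
      }
      out <- c(out, (lo + hi) / 2)
    }
    out
  }
  for (fr in axis_roots(seq(0, F_max, length.out = axis_resolution),
                        function(x) macro_rhs(x, 0, params)$dF)) {
    hits <- c(hits, list(data.frame(F = fr, S = 0,
                                    norm = norm_at(fr, 0))))
  }
  for (sr in axis_roots(seq(0, S_max, length.out = axis_resolution),
                        function(x) macro_rhs(0, x, params)$dS)) {
    hits <- c(hits, list(data.frame(F = 0, S = sr,
                                    norm = norm_at(0, sr))))
  }

  # --- interior sweep: cells where both nullclines cross -----------------
  # grid points are allocated per axis so that cells come out near-square
  # in absolute biomass units (strongly anisotropic cells let slanted
  # nullclines slip between corners); the point budget is resolution^2
  h <- sqrt(F_max * S_max) / resolution
  nF <- min(max(as.integer(round(F_max / h)), 60L), 1500L)
  nS <- min(max(as.integer(round(S_max / h)), 60L), 1500L)
  Fg <- seq(0, F_max, length.out = nF)
  Sg <- seq(0, S_max, length.out = nS)
  # on the axes the own-species rate is identically zero, so cells with
  # corners at F = 0 (or S = 0) can never register a sign change; nudge
  # the first grid line just off the axis (the axes themselves are
  # covered by the dense 1-D scans above)
  Fg[1L] <- Fg[2L] * 1e-3
  Sg[1L] <- Sg[2L] * 1e-3
  r <- macro_rhs(rep(Fg, times = nS), rep(Sg, each = nF), params)
  DF <- matrix(r$dF, nrow = nF)
  DS <- matrix(r$dS, nrow = nF)
  DF[!is.finite(DF)] <- NA_real_
  DS[!is.finite(DS)] <- NA_real_
  corner_flip <- function(M) {
    a <- M[-nF, -nS]; b <- M[-1L, -nS]
    c2 <- M[-nF, -1L]; d <- M[-1L, -1L]
    lo <- pmin(a, b, c2, d); hi <- pmax(a, b, c2, d)
    !is.na(lo) & !is.na(hi) & lo < 0 & hi > 0
  }
  cand <- which(corner_flip(DF) & corner_flip(DS), arr.ind = TRUE)
  cw_F <- Fg[2L] - Fg[1L]
  cw_S <- Sg[2L] - Sg[1L]
  pen <- function(y) {
    yc <- pmax(y, 0)
    v <- norm_at(yc[1L], yc[2L])
    if (!is.finite(v)) return(.Machine$double.xmax)
    v + sum(pmax(-y, 0)) * 1e3
  }
  for (k in seq_len(nrow(cand))) {
    f0 <- Fg[cand[k, 1L]] + cw_F / 2
    s0 <- Sg[cand[k, 2L]] + cw_S / 2
    opt <- stats::optim(c(f0, s0), pen, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-15,
                                       parscale = c(cw_F, cw_S)))
    f0 <- max(opt$par[1L], 0); s0 <- max(opt$par[2L], 0)
    val <- norm_at(f0, s0)
    scale <- max(residual_scale_F(f0, s0, params),
                 residual_scale_S(f0, s0, params))
    if (val < threshold * scale) {
      hits <- c(hits, list(data.frame(F = f0, S = s0, norm = val)))
    }
  }
  out <- if (length(hits) > 0L) do.call(rbind, hits)
         else data.frame(F = numeric(0), S = numeric(0), norm = numeric(0))
  # distinct candidates can descend to the same root: merge duplicates,
  # keeping the best; the radius is far below the cell size so genuinely
  # distinct roots are never collapsed
  if (nrow(out) > 1L) {
    tol_F <- max(1e-6, 1e-7 * F_max)
    tol_S <- max(1e-6, 1e-7 * S_max)
    out <- out[order(out$norm), , drop = FALSE]
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out) - 1L)) {
      if (!keep[i]) next
      later <- (i + 1L):nrow(out)
      close <- abs(out$F[later] - out$F[i]) <= tol_F &
        abs(out$S[later] - out$S[i]) <= tol_S
      keep[later][close] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
    out <- out[order(out$F, out$S), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "cell_F") <- cw_F
  attr(out, "cell_S") <- cw_S
  class(out) <- c("macro_oracle", "data.frame")
  out
}
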