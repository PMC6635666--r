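#' Algebraic nutrient closure
#'
#' Water-column nutrients are not an independent stock: they are tied to
#' the current plant biomasses by
#' \deqn{N = N_0 - m_F (F - F_0) - m_S (S - S_0),}
#' so that the quantity \eqn{m_F F + m_S S + N} is conserved exactly along
#' every trajectory.  The closure is applied as printed and may return a
#' negative value when biomass grows large; it is deliberately not clamped
#' (clamping would silently break the conservation identity), and negative
#' nutrients are self-correcting because they turn the growth terms
#' negative.  [simulate_macro()] flags trajectories that visit `N < 0`.
#'
#' @param F floating plant biomass (vectorised).
#' @param S submerged plant biomass (vectorised).
#' @param params a [macro_params()] object.
#' @return Nutrient mass, same length as `F`/`S`.
#' @examples
#' p <- macro_params()
#' nutrient_level(p$F0, p$S0, p)  # == N0 at the initial state
#' @export
nutrient_level <- function(F, S, params) {
  params$N0 - params$m_F * (F - params$F0) - params$m_S * (S - params$S0)
}

#' Nutrient-dependent intraspecific competition
#'
#' Self-limitation relaxes as nutrients become more available:
#' \deqn{c(N) = c_0 \exp(-e N).}
#' The value is strictly decreasing in `N` (for `c0, e > 0`), lies in
#' `(0, c0]` for `N >= 0`, and never exceeds `c0` there.
#'
#' @param N nutrient mass (vectorised).
#' @param c0 maximum competition rate, 1/(biomass time).
#' @param e decay strength, 1/mass.
#' @return Competition rate, same length as `N`.
#' @examples
#' competition(0, 1, 1)   # 1
#' competition(1, 1, 1)   # exp(-1)
#' @export
competition <- function(N, c0, e) {
  c0 * exp(-e * N)
}

#' Right-hand side of the two-species competition model
#'
#' Evaluates the growth equations
#' \deqn{dF/dt = -l_F F + a_F N F - c_F(N) F^2 - B F}
#' \deqn{dS/dt = -l_S S + a_S N S - c_S(N) S^2}
#' with `N` always recomputed internally from `(F, S)` via
#' [nutrient_level()] -- callers never pass `N`.  Both components vanish
#' identically when the corresponding biomass is zero, so extinction is an
#' absorbing state of the exact dynamics.
#'
#' @inheritParams nutrient_level
#' @return A list with vector components `dF` and `dS` (biomass/time).
#' @examples
#' p <- macro_params()
#' macro_rhs(1, 1, p)  # growth rates at the symmetric initial state
#' @export
macro_rhs <- function(F, S, params) {
  N <- nutrient_level(F, S, params)
  cF <- competition(N, params$c_F0, params$e_F)
  cS <- competition(N, params$c_S0, params$e_S)
  list(dF = -params$l_F * F + params$a_F * N * F - cF * F^2 - params$B * F,
       dS = -params$l_S * S + params$a_S * N * S - cS * S^2)
}

#' Jacobian of the model at a state
#'
#' Closed-form 2x2 Jacobian of [macro_rhs()] with respect to `(F, S)`,
#' including the chain-rule contributions through the nutrient closure
#' (`dN/dF = -m_F`, `dN/dS = -m_S`, and the `N`-dependence of the
#' competition coefficients).  Used for linear stability classification;
#' tested against central finite differences.
#'
#' @inheritParams nutrient_level
#' @return A 2x2 numeric matrix, rows/cols ordered `(F, S)`.
#' @seealso [classify_stability()]
#' @export
macro_jacobian <- function(F, S, params) {
  N <- nutrient_level(F, S, params)
  cF <- competition(N, params$c_F0, params$e_F)
  cS <- competition(N, params$c_S0, params$e_S)
  # d c_X / dF = (-e_X c_X) * dN/dF etc.; dN/dF = -m_F, dN/dS = -m_S
  j11 <- -params$l_F - params$B + params$a_F * N - params$a_F * params$m_F * F -
    2 * cF * F - params$e_F * cF * params$m_F * F^2
  j12 <- -params$a_F * params$m_S * F - params$e_F * cF * params$m_S * F^2
  j21 <- -params$a_S * params$m_F * S - params$e_S * cS * params$m_F * S^2
  j22 <- -params$l_S + params$a_S * N - params$a_S * params$m_S * S -
    2 * cS * S - params$e_S * cS * params$m_S * S^2
  matrix(c(j11, j21, j12, j22), nrow = 2L,
         dimnames = list(c("F", "S"), c("F", "S")))
}
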