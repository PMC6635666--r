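#' Model parameters for the floating--submerged macrophyte competition model
#'
#' Constructs and validates the full parameter set of the two-species
#' competition model: mortality, nutrient-uptake and intraspecific
#' competition rates for the floating (`_F`) and submerged (`_S`) plant,
#' the biocontrol mortality rate `B` applied to the floating plant, and the
#' initial stocks `N0`, `F0`, `S0` that anchor the algebraic nutrient
#' closure.  Units are abstract (biomass, mass, time); the model is
#' qualitative and scales are not fixed.
#'
#' The defaults are the bundled baseline parameterisation (see
#' `system.file("extdata", "baseline.yaml", package = "macroshift")`):
#' equal natural mortality for the two species, a faster-growing and more
#' strongly self-limited floating plant, and a submerged plant that locks
#' up an order of magnitude more nutrient per unit biomass
#' (`m_S = 0.1` vs `m_F = 0.01`).
#'
#' @param l_F,l_S natural mortality rates, 1/time.
#' @param a_F,a_S nutrient-uptake (growth) rates, 1/(mass time).
#' @param c_F0,c_S0 maximum intraspecific competition, 1/(biomass time).
#'   Must be strictly positive: self-limitation is what bounds the dynamics.
#' @param e_F,e_S decay strength of competition with nutrients, 1/mass.
#' @param m_F,m_S per-biomass effect on water-column nutrients, mass/biomass.
#' @param B biocontrol mortality rate on floating plants, 1/time.
#' @param N0 initial nutrient availability, mass.
#' @param F0,S0 initial floating and submerged biomass.
#'
#' @return An object of class `macro_params`: a named list of the fourteen
#'   parameters, validated (all non-negative, `c_F0 > 0`, `c_S0 > 0`).
#' @examples
#' p <- macro_params()            # baseline, B = 0
#' p2 <- macro_params(B = 2.2)    # strong biocontrol pressure
#' @seealso [nutrient_level()], [macro_rhs()], [simulate_macro()]
#' @export
macro_params <- function(l_F = 1, l_S = 1, a_F = 1, a_S = 0.5,
                         c_F0 = 1, c_S0 = 0.5, e_F = 1, e_S = 1,
                         m_F = 0.01, m_S = 0.1,
                         B = 0, N0 = 5, F0 = 1, S0 = 1) {
  p <- list(l_F = l_F, l_S = l_S, a_F = a_F, a_S = a_S,
            c_F0 = c_F0, c_S0 = c_S0, e_F = e_F, e_S = e_S,
            m_F = m_F, m_S = m_S, B = B, N0 = N0, F0 = F0, S0 = S0)
  validate_macro_params(p)
}

#' @rdname macro_params
#' @param x a named list (or `macro_params`) to validate/coerce.
#' @export
as_macro_params <- function(x) {
  if (inherits(x, "macro_params")) return(x)
  stopifnot(is.list(x))
  unknown <- setdiff(names(x), macro_param_names())
  if (length(unknown) > 0L) {
    stop("unknown parameter key(s): ", paste(sQuote(unknown), collapse = ", "),
         call. = FALSE)
  }
  do.call(macro_params, x)
}

macro_param_names <- function() {
  c("l_F", "l_S", "a_F", "a_S", "c_F0", "c_S0", "e_F", "e_S",
    "m_F", "m_S", "B", "N0", "F0", "S0")
}

validate_macro_params <- function(p) {
  for (nm in macro_param_names()) {
    v <- p[[nm]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter ", sQuote(nm), " must be a single finite number",
           call. = FALSE)
    }
    p[[nm]] <- as.numeric(v)
    if (p[[nm]] < 0) {
      stop("parameter ", sQuote(nm), " must be non-negative (got ",
           format(p[[nm]]), ")", call. = FALSE)
    }
  }
  if (p$c_F0 <= 0 || p$c_S0 <= 0) {
    stop("'c_F0' and 'c_S0' must be strictly positive: without ",
         "self-limitation the dynamics are unbounded", call. = FALSE)
  }
  structure(p[macro_param_names()], class = "macro_params")
}

#' @export
print.macro_params <- function(x, ...) {
  cat("<macro_params>\n")
  cat(sprintf("  mortality     l_F = %-8g l_S = %g\n", x$l_F, x$l_S))
  cat(sprintf("  uptake        a_F = %-8g a_S = %g\n", x$a_F, x$a_S))
  cat(sprintf("  competition   c_F0 = %-7g c_S0 = %-7g e_F = %-6g e_S = %g\n",
              x$c_F0, x$c_S0, x$e_F, x$e_S))
  cat(sprintf("  nutrient use  m_F = %-8g m_S = %g\n", x$m_F, x$m_S))
  cat(sprintf("  biocontrol    B = %g\n", x$B))
  cat(sprintf("  initial state N0 = %-8g F0 = %-8g S0 = %g\n",
              x$N0, x$F0, x$S0))
  invisible(x)
}

# total conserved nutrient stock: m_F*F + m_S*S + N is constant and equals
# this value along every trajectory (algebraic closure, so exact)
nutrient_total <- function(params) {
  params$N0 + params$m_F * params$F0 + params$m_S * params$S0
}

# parameter-derived search bound per axis: every equilibrium with positive
# biomass needs a_X N > 0, hence N > 0, hence m_X X < total nutrient stock;
# the bound is the biomass at which that species alone would exhaust it
biomass_bound <- function(params, axis = c("F", "S")) {
  axis <- match.arg(axis)
  m <- if (axis == "F") params$m_F else params$m_S
  if (m <= 0) {
    # no nutrient feedback on this axis; fall back to a large box
    return(1000 * max(1, params$N0, params$F0, params$S0))
  }
  nutrient_total(params) / m
}
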