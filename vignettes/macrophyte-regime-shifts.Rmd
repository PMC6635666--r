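---
title: "Modelling the regime shift from floating to submerged invasive macrophytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the regime shift from floating to submerged invasive macrophytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macroshift)
```

## The model

Freshwater systems invaded by floating macrophytes (water lettuce, water
hyacinth and their relatives) are increasingly managed with classical
biological control: a host-specific herbivore is released and the
floating mat collapses.  Field surveys have repeatedly found that the
collapse is followed not by recovery of native vegetation but by
dominance of *submerged* invasive plants, which capitalise on the
nutrients, light and space released by the decomposing mat.  `macroshift`
implements a deliberately minimal competition model of that regime
shift and the machinery needed to analyse it quantitatively: trajectory
simulation, equilibrium and stability analysis, and bifurcation scans
over the biocontrol pressure and the nutrient status of the water.

Two biomass stocks are modelled, floating plants $F$ and submerged
plants $S$:

$$\frac{dF}{dt} = -l_F F + a_F N F - c_F(N)\,F^2 - B F$$
$$\frac{dS}{dt} = -l_S S + a_S N S - c_S(N)\,S^2$$

Each species has a natural mortality rate $l_X$, a nutrient-limited
growth rate $a_X N$, and a quadratic self-limitation whose coefficient
relaxes as nutrients become available:

$$c_X(N) = c_{X0}\,e^{-e_X N}.$$

Biological control acts on the floating plant only, as the constant
extra mortality rate $B$; the control agents are not a dynamic
population.  Water-column nutrients are not an independent stock.  They
are tied to the plant biomasses by the algebraic closure

$$N = N_0 - m_F (F - F_0) - m_S (S - S_0),$$

so the quantity $m_F F + m_S S + N$ is conserved exactly along every
trajectory.  The state vector is $(F, S)$ only; $N$ is derived
everywhere, never integrated.  This removes a spurious degree of
freedom and makes the conservation identity a machine-precision
invariant that the test suite checks on every trajectory it produces.

Interspecific competition is entirely indirect, through the shared
nutrient pool: a large floating mat depresses $N$, which slows
submerged growth *and* tightens submerged self-limitation, and vice
versa.  The asymmetry of the species is carried by the parameter
values, not the equations: the floating plant grows faster
($a_F > a_S$) and is more strongly self-limited ($c_{F0} > c_{S0}$),
while the submerged plant locks up an order of magnitude more nutrient
per unit biomass ($m_S \gg m_F$).

Units are abstract (biomass, mass, time).  The model is qualitative by
construction; nothing in this package should be read as a quantitative
prediction for a particular water body.

### Degenerate and extreme states

The closure can return $N < 0$ when biomass grows very large.  We do
not clamp it: clamping would silently break the printed algebraic
relation and the conservation identity.  Negative $N$ is
self-correcting — it makes the net growth terms negative — and
`simulate_macro()` raises a warning flag on any trajectory that visits
it, so the user knows the run left the model's sensible regime.

Because both equations are multiplicative in the species' own biomass,
extinction is absorbing and trajectories cannot cross zero in exact
arithmetic.  Any negative biomass produced by a discrete integration
step is therefore integrator error: it is clamped to zero and flagged.
A species is reported extinct when its biomass stays below $10^{-9}$
for the remainder of a run — far below any dynamically meaningful scale
here, but needed to state "complete switch" results crisply.

## Baseline parameterisation and calibration

The bundled baseline (`inst/extdata/baseline.yaml`, the defaults of
`macro_params()`) uses the published qualitative rate constants:
$l_F = l_S = 1$, $a_F = 1$, $a_S = 0.5$, $c_{F0} = 1$, $c_{S0} = 0.5$,
$e_F = e_S = 1$, $m_F = 0.01$, $m_S = 0.1$, with both plants starting
at the same biomass $F_0 = S_0 = 1$.

The original description of the model leaves the actual nutrient levels
of its "high" and "low" scenarios unspecified (scales are not fixed),
so the two nutrient settings and the non-zero biocontrol rates bundled
here are calibration choices made once by this package:

* $N_{0,\text{high}} = 5$, $N_{0,\text{low}} = 2.5$.  The low setting
  must keep both plants viable at $B = 0$ (the submerged plant needs
  $a_S N > l_S$, i.e. $N > 2$ at these rates, at its own equilibrium)
  while being far enough below the high setting that the
  nutrient-dependent contrasts are unambiguous.
* $B$ levels $0$, $0.5$ and $2.2$.  Zero is the only value fixed by
  the source scenario.  The intermediate level is half the dominance
  threshold ($B^{\mathrm{dom}} = 1$, next section), so it shows a
  floating-dominant system under visible pressure.  The strong level
  sits just above the floating-exclusion threshold at high nutrients
  ($B^{\mathrm{excl}} \approx 2.02$), so it produces the complete
  switch in *both* nutrient settings while retaining a visible
  coexistence phase before the crossing.

With these choices the six-panel grid (`panel_grid()`) spans the full
qualitative repertoire: floating plateau dominance without control, a
sharper submerged rise under intermediate control, and a complete
dominance switch with floating extinction under strong control, with
all slopes much reduced at low nutrients.

```{r panels, eval = FALSE}
pg <- panel_grid()
pg$summary
pg$checks
plot(pg)
```

## Two critical thresholds, not one

A central finding of the implementation is that this model has **two
distinct critical biocontrol rates**, and they behave differently:

**The dominance flip** $B^{\mathrm{dom}}$: the rate at which the larger
steady-state biomass switches from floating to submerged.  At an
interior (coexistence) equilibrium the per-capita conditions invert to

$$F^* = \frac{a_F N^* - l_F - B}{c_F(N^*)}, \qquad
  S^* = \frac{a_S N^* - l_S}{c_S(N^*)},$$

and at the baseline rates a coincidence — $a_F c_{S0} = a_S c_{F0}$
together with $e_F = e_S$ — makes the gap collapse to
$F^* - S^* = (1 - B)\,e^{N^*}$ (in these units).  The flip therefore
sits at exactly $B = 1$, *independent of nutrient loading*.  The
package does not assume this: `scan_B()` and `critical_biocontrol()`
locate the flip by bisection on the simulated long-run outcome, and the
test suite checks that the computed values at high and low $N_0$ agree
to the bisection width.

**The exclusion threshold** $B^{\mathrm{excl}}$: the rate beyond which
the floating plant cannot persist at all and the switch is complete.
It is the transcritical point at which the floating invasion rate into
the submerged-only state, $a_F N^*_S - l_F - B$, changes sign.  Because
the submerged equation does not involve $B$, the submerged-only
nutrient level $N^*_S$ is $B$-independent and

$$B^{\mathrm{excl}} = a_F N^*_S - l_F.$$

$N^*_S$ increases with $N_0$, so this threshold *does* depend on
nutrient loading: $B^{\mathrm{excl}} \approx 2.02$ at $N_0 = 5$ versus
$\approx 1.30$ at $N_0 = 2.5$.  Less biocontrol pressure is needed for
the complete switch in nutrient-poor water — the interaction of
bottom-up and top-down drivers that motivates the model.  The sweep
`critical_B_vs_N0()` reports both thresholds per nutrient level, and
the monotonicity claim is tested on the exclusion threshold, which is
the one that carries it.  For $1 < B < B^{\mathrm{excl}}$ the system
settles into submerged-dominant coexistence: the submerged plant leads
but the floating plant persists.

```{r thresholds, eval = FALSE}
critical_B_vs_N0(macro_params(), c(2.5, 3.125, 3.75, 4.375, 5))
```

## Equilibria, stability, and the brute-force oracle

`find_equilibria()` enumerates the trivial state $(0,0)$, the
single-species branches, and coexistence roots.  The boundary branches
are one-dimensional per-capita conditions solved by dense sign-change
scans plus bracketed root refinement.  For coexistence we do not run a
2-D Newton search from a lattice: the per-capita conditions invert in
closed form to $F(N)$ and $S(N)$ above, reducing the problem to a
single scalar equation in $N$ (the closure).  A dense scan of that
scalar equation cannot miss roots in the scanned interval, which a
lattice of 2-D starts can.  All roots are polished by Newton iteration
with the analytic Jacobian.

The search region is principled: any equilibrium with positive biomass
needs $a_X N > 0$, hence $N > 0$, so the conservation identity caps
each biomass at the level that would single-handedly exhaust the total
nutrient stock, $F \le (N_0 + m_F F_0 + m_S S_0)/m_F$ and analogously
for $S$.

Stability is classified from the eigenvalues of the analytic $2\times2$
Jacobian, which includes the chain-rule contributions through the
nutrient closure ($\partial N/\partial F = -m_F$, etc.).  The verdict
uses a marginality tolerance of $10^{-8}$ on the real parts, separating
genuine bifurcation points from floating-point noise.  Analytic entries
are tested against central finite differences at every equilibrium
found.

`grid_oracle()` is the definitional cross-check, deliberately built on
a different principle so that the two routes can disagree: dense 1-D
sign-change scans of the raw growth rates along each axis, plus a
marching-squares sweep of the interior flagging every near-square cell
whose corners show a sign change in *both* components (a nullcline
crossing), refined by a derivative-free simplex descent on the norm of
the rate vector.  Two implementation details matter and were found the
hard way: cells with corners exactly on an axis can never register a
sign change of the own-species rate (it is identically zero there), so
the first interior grid line is nudged off each axis; and cells must be
near-square in absolute biomass units, because strongly anisotropic
cells let slanted nullclines slip between corners.  Root-finder and
oracle are required to agree one-to-one (within one oracle cell) on the
baseline set and on randomized parameter sets drawn within a factor of
four of it.

## Numerical choices

* **Adaptive integration** uses `deSolve::ode(method = "lsoda")` at
  relative tolerance $10^{-8}$ (absolute $10^{-12}$).  LSODA's
  automatic stiff/non-stiff switching keeps the long quiescent plateau
  after the shift cheap and robust; the explicit Runge–Kutta codes in
  the same library were observed to stall once a trajectory sits
  numerically on a stable equilibrium.
* **Fixed-step Euler** (default $dt = 0.01$) is provided for fidelity
  to the stock-and-flow (system-dynamics) software tradition in which
  models of this family are usually built, where the published step
  size is typically unstated.  The test suite verifies first-order
  convergence of the Euler mode toward the adaptive solution (the error
  halves when $dt$ does), so the two modes are mutually validating.
* **Sampling**: trajectories are reported on a fixed grid of 1000
  evenly spaced samples regardless of solver internals, which keeps
  event detection and CSV output stable.
* **Termination**: runs stop at $t_{\mathrm{end}} = 200$ time units by
  default, or earlier once both growth rates stay below $10^{-10}$ for
  a full sample interval (steady-state early stop) — an explicit
  criterion replacing the visual "has it plateaued" judgement.
* **Switch detection**: the dominance switch is the first crossing
  where $S$ strictly exceeds $F$ after having been at or below it,
  refined by linear interpolation between samples.  An exact tie is
  never a switch, which keeps the symmetric start $F_0 = S_0$ from
  producing a spurious event at $t = 0$.  A trajectory that starts
  submerged-dominant is reported distinctly rather than as an event.
  Under very strong control the floating plant declines from the first
  instant and the switch time is legitimately $0$.
* **Thresholds**: bisection on a categorical simulation outcome, with
  the bracket invariant (endpoints always differ) maintained and the
  interval refined to $10^{-4}$ of the search span.  Residual checks at
  equilibria are relative to the magnitude of the constituent terms:
  at order-one scales this is the absolute $10^{-9}$ criterion, while
  at the large biomass scales that random parameter draws can produce,
  double precision cannot deliver absolute $10^{-9}$ and a relative
  check is the honest equivalent.
* **Determinism**: the package contains no random number generation
  anywhere.  The bistability probe uses a deterministic lattice of
  starts, and two runs of any scenario produce byte-identical CSV
  output.  Randomness appears only in the test suite and the
  acceptance script, which draw perturbed parameter sets under a fixed
  seed.

## Bistability

Whether this system is truly bistable at fixed parameters (hysteresis,
history-dependence) or has a single attractor that moves with $B$ is
not decidable from its qualitative description, so
`bistability_probe()` measures it rather than assuming either reading.
Starts are laid on a deterministic lattice inside the conservation
simplex; the initial nutrient stock is adjusted per start so that every
trajectory lives on the *same* vector field (the closure ties $N$ to
the initial state, so naively varying $F_0, S_0$ would change the
system being probed).  At the baseline rates and $B = 0$ the verdict is
monostable: all starts converge to the floating-dominant coexistence
equilibrium.  The "two basins" picture is, in this regime, a statement
about the system *across* biocontrol levels, not at a fixed one.

## What the bundled scenarios do and do not show

The bundled grid demonstrates the model's qualitative repertoire under
the baseline rates: dominance patterns, switch timing, slope contrasts,
and the nutrient dependence of the exclusion threshold.  Because the
model is abstract — no light competition, no water chemistry, no
decomposer pool, no dynamic herbivore population, no seasonality, no
space — passing these checks says the *implementation* reproduces the
*model's* claimed behaviour, not that a particular field system will
behave this way.  Transferring the conclusions to a real water body
requires the quantitative parameterisation the model deliberately does
not attempt.

Known limitations of the analysis machinery: the equilibrium search is
bounded by the nutrient-exhaustion box and scans at finite resolution,
so root pairs separated by less than the scan spacing could in
principle be missed (the oracle cross-check bounds this risk); basins
of attraction are sampled, not computed; and no numerical continuation
of equilibrium branches is attempted — thresholds are located by
bisection on simulation outcomes instead.
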