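---
title: "The SEWIR model: equilibria, stability, and intervention analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The SEWIR model: equilibria, stability, and intervention analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sewir)
```

## The model

The package implements a five-compartment epidemic model in which the
classical exposed class is split in two: unquarantined exposed individuals
$E$, who will go on to develop symptoms, and quarantined exposed individuals
$W$, who have been placed in medical isolation before becoming infectious to
others. Susceptibles $S$ are vaccinated with success probability $m$,
infected individuals $I$ transmit at rate $\beta$, and a *government control
rate* $k_1$ moves exposed individuals into quarantine:

$$
\begin{aligned}
S' &= -\beta I S + \Lambda(1-m) + k_2 W - mS - \mu S\\
E' &= \beta I S - (k_1+\varepsilon+\mu)E\\
W' &= k_1 E - (\vartheta+k_2+\mu)W\\
I' &= \varepsilon E - (\vartheta+\gamma+\mu)I\\
R' &= \vartheta W + \vartheta I + m(\Lambda+S) - \mu R
\end{aligned}
$$

$\Lambda$ is the inflow of newborns and migrants (individuals/day), of whom a
fraction $m$ is vaccinated directly into $R$; $\mu$ and $\gamma$ are natural
and disease-induced mortality; $\varepsilon$ is the E-to-I conversion rate;
$\vartheta$ the recovery rate (identical for $W$ and $I$); and $k_2$ the rate
at which quarantined individuals clear the virus on their own and return to
$S$. All rates are per day. The model is deterministic and continuous: no
age or spatial structure, no demographic stochasticity, no fitting to
incidence data.

One structural reading deserves emphasis. The recovery equation's
vaccination inflow is taken as $m(\Lambda + S)$ — i.e. both the vaccinated
fraction of new entrants, $m\Lambda$, and the vaccinated susceptibles, $mS$,
land in $R$. This is forced by bookkeeping: the $S$ equation removes $mS$
and the inflow splits as $\Lambda(1-m) + m\Lambda$, and only this reading
makes the total population obey
$N' = \Lambda - \gamma I - \mu N$ exactly. The package asserts that identity
to machine precision on randomized states (see `test-model.R`).

Because the $R$ equation decouples, the analysis lives on the reduced
$(S, E, W, I)$ system, restricted to the biologically feasible region
$\Omega = \{S,E,W,I \ge 0,\; S+E+W+I \le \Lambda(1-m)/\mu\}$, which is
forward-invariant (`feasible_bound()`, `in_feasible_region()`).

## Reproduction number and equilibria

With compound outflow rates $T_1 = \mu + k_1 + \varepsilon$,
$T_2 = \mu + \vartheta + \gamma$, $T_3 = \mu + \vartheta + k_2$ and
$\theta = m + \mu$, the disease-free equilibrium has
$S_0 = \Lambda(1-m)/(m+\mu)$ and the basic reproduction number is

$$R_0 = \frac{\beta \varepsilon S_0}{T_1 T_2}.$$

`r0_closed_form()` evaluates this directly; `r0_ngm()` rebuilds it as the
spectral radius of the next-generation matrix $FV^{-1}$ of the infected
subsystem $(E, I)$, computed by numerical eigendecomposition. The two routes
are independent implementations and the package property-tests their
agreement to $10^{-10}$ relative. Above threshold ($R_0 > 1$) the unique
endemic equilibrium is returned in closed form by `endemic_equilibrium()`,
deliberately evaluated in the factored form
$E^* = T_3 T_1 T_2 \theta (1-R_0) / [\beta\varepsilon(k_1 k_2 - T_1 T_3)]$
(both factors negative above threshold) rather than algebraically
simplified, so printed values line up digit-for-digit with the closed-form
derivation; a residual check confirms it is a fixed point to
$10^{-9}\max(1,\Lambda)$. At $R_0 = 1$ exactly no endemic equilibrium is
reported (the existence condition is strict). The combination
$k_1 k_2 - T_1 T_3$ is algebraically negative for every admissible parameter
set; `derived_rates()` asserts it rather than trusting it.

## Stability machinery

`classify_stability()` classifies each equilibrium twice and cross-checks:

* **Eigenvalues.** The $4\times4$ Jacobian (in $(E, I, S, W)$ order) is
  assembled in closed form — at the disease-free point its spectrum always
  contains $-\theta$ and $-T_3$ exactly, with the remaining pair solving
  $\lambda^2 + (T_1+T_2)\lambda + T_1 T_2 (1-R_0) = 0$, so stability flips
  precisely at $R_0 = 1$.
* **Routh–Hurwitz.** `hurwitz_minors()` builds the Hurwitz matrix with the
  alternating row convention $(b_1, b_3, b_5, \ldots)/(1, b_2, b_4, \ldots)$,
  zero-padding $b_k = 0$ for $k > n$, and returns its leading principal
  minors $\Phi_1 \ldots \Phi_n$. The implementation is validated against a
  brute-force oracle: random polynomials of degree up to six built from
  known roots, with the minor-positivity verdict compared to the actual
  root signs.

At the endemic point the quartic coefficients $b_1 \ldots b_4$ are also
available in closed form (`char_coeffs_endemic()`) and are property-tested
against the numerically extracted characteristic polynomial to $10^{-8}$
relative. A disagreement between the Hurwitz and eigenvalue verdicts raises
an internal-consistency error rather than picking a winner. Eigenvalue real
parts within $10^{-9}$ of zero are classified `"marginal"`, never silently
`"stable"`; the tolerance is an explicit argument.

Global stability of the disease-free state below threshold rests on the
Lyapunov function $\mathcal{L} = \varepsilon E + T_1 I$, whose exact
derivative along the flow is
$\mathcal{L}' = I(\beta\varepsilon S - T_1 T_2)$. `lyapunov()` exposes this
equality form rather than the $S \le S_0$ inequality bound, because the
bound's premise is a property of the sampled state, not a theorem about
every point of $\Omega$ at finite time: the diagnostic therefore *reports*
whether $S > S_0$ (`s_exceeds_s0`) instead of assuming it away. Global
convergence of the endemic state is probed by simulation from randomized
initial conditions — a numerical check, not a proof.

## Simulation and interventions

`sewir_simulate()` integrates the full five-compartment system with
`deSolve`, by default the adaptive Dormand–Prince 4(5) pair with
`rtol = 1e-8`, `atol = 1e-10`; a fixed-step RK4 (`method = "rk4"`) exists
for bit-stable comparison runs and fixture regeneration. Interventions are
piecewise-constant parameter switches (`sewir_schedule()`): right-continuous,
instantaneous in the parameters, continuous in the state, with the
integrator restarted exactly at each switch time. The convergence contract —
halving both tolerances moves no reported value by more than $10^{-6}$
relative — is asserted on all four single-run scenarios, with relative
differences floored at one individual so that compartments decaying to
$10^{-10}$ do not dominate the ratio. Output components in
$(-10\,\mathrm{atol}, 0)$ are clipped to zero; anything more negative
signals a genuine defect (the orthant is invariant for the exact flow) and
raises an error with the failure time. The default output grid of 0.1 day
resolves the sharp early wave crests; peak comparisons use 0.05.

`summarise_trajectory()` reports, per compartment, the grid maximum
(`peak`, first-grid-point tie-break), the *outbreak peak* (largest interior
local maximum), threshold-crossing times with linear interpolation between
bracketing grid points, the terminal state, and optionally the maximum
deviation from a reference equilibrium over the final window. Two peak
notions are needed because a compartment initialized above its epidemic
wave — quarantined exposures start at 15 in the packaged scenarios — first
declines, so its grid maximum is the initial condition while the
epidemiologically meaningful crest is interior. `compare_peaks()` therefore
defaults to outbreak peaks.

## The packaged scenarios

Six configurations (`sewir_case()`) share the baseline constants
($\Lambda = 15$, $\beta = 0.5$, $\mu = 0.08$, $\varepsilon = 0.8$,
$\gamma = 0.06$, $\vartheta = 0.8$, $k_2 = 0.01$; shipped in
`extdata/params_table1.yaml`) and the initial state
$(S, E, W, I, R) = (120, 0, 15, 1, 0)$. The source the constants derive
from lists four compartment names against five initial values; the package
maps the tuple positionally onto $(S, E, W, I, R)$ — so $W(0) = 15$,
$I(0) = 1$ — records this as an interpretive choice, and lets scenario
configurations override the initial state with named fields.

* **case1** ($m=0.8$, $k_1=0.6$): $R_0 = 0.9802 < 1$, extinction;
* **case2** ($m=0.35$, $k_1=0.3$): $R_0 = 8.1769$, convergence to the
  endemic state $(E^*, I^*, S^*, W^*) = (7.2730, 6.1898, 2.7730, 2.4516)$;
* **case3** ($m=0.35$, $k_1=0.6$, $R_0 = 6.5194$; $m \to 0.8$ on day 220):
  the switch drops $R_0$ to $0.9802$ and the epidemic goes extinct;
* **case4** (as case3 but early $k_1 = 0.2$; both controls raised on
  day 220): comparing with case3 isolates the effect of early quarantine
  intensity — the W wave crest is about 93.4% higher and the I crest about
  17.7% lower under the stronger early control;
* **case5/case6**: one control fixed, the other varied over three
  representative values. These values ($m \in \{0.78, 0.85, 0.92\}$ at
  $k_1 = 0.8$; $k_1 \in \{0.6, 0.8, 1.0\}$ at $m = 0.8$) are the package's
  own choices, picked to keep $R_0 < 1$ (which requires $m > 0.775$ and
  $k_1 > 0.571$ respectively at the baseline constants); they are
  illustrative, not canonical.

Simulation horizons are 500 days for the convergence scenarios (long enough
for the slow subthreshold mode, $|\lambda| \approx 0.011$/day in case1, to
decay below $10^{-3}$ individuals), 400 days for the intervention scenarios
and 200 for the families.

```{r scenario}
res <- run_case(sewir_case("case3"))
res$summary
```

One scenario claim deliberately fails reproduction and is kept visible
rather than papered over. The source narrative for case3 has $I(t)$ and
$W(t)$ dropping below one individual "around day 260", forty days after the
switch. Under the equations as printed this cannot happen: when $m$ jumps to
0.8 the susceptible inflow $\Lambda(1-m)$ falls from 9.75 to 3/day while the
outflow $mS$ jumps, so $S$ collapses within a few days, transmission
collapses with it, and both compartments cross 1 near day 224 — confirmed by
two independent integrators at tight tolerances. The corresponding
acceptance test asserts the 240–280-day band faithfully and is expected to
fail; the scenario tests assert the behaviour the model actually produces
(extinction shortly after the switch).

## Sensitivity of the reproduction number

`r0_surface()` evaluates the closed-form $R_0$ over an $(m, k_1)$ grid
(default $[0,1]^2$ in steps of 0.01) and `r0_sensitivity()` gives
central-difference derivatives at an operating point:

```{r sensitivity}
r0_sensitivity(sewir_params(m = 0.35, k1 = 0.3))
```

$|\partial R_0/\partial m| > |\partial R_0/\partial k_1|$ throughout the
explored region: per unit increase, raising vaccination success buys more
reduction in $R_0$ than raising the quarantine rate, because $m$ acts both
on the susceptible pool and on the inflow while $k_1$ only shortens the
infectious window of the exposed class.

## Numerical choices and limitations

* Parameter validation is strict — out-of-range values are rejected, never
  clamped. Degenerate requests (endemic analysis at $R_0 \le 1$, singular
  transition matrix) raise typed errors.
* Peak times use a first-grid-point tie-break; thresholds interpolate
  linearly between grid points, so crossing times are accurate to well
  under the grid spacing for smooth trajectories.
* The test suite's randomized property checks run at fixed seeds with a few
  dozen to a thousand replicates per property and problem sizes of a few
  hundred days of integration — sizes chosen to probe the parameter domain
  densely while keeping a full run in well under a minute per file.
* What passing tests show is internal consistency of the deterministic
  model and exact reproduction of its closed forms — not realism of the
  compartmental assumptions. There is no age/contact structure, no
  stochastic extinction at small counts (compartments decay continuously
  through values below one individual), vaccination is modeled as a single
  success probability, and quarantine is leak-free apart from the $k_2$
  return path. Cost or optimal-control objectives are out of scope: the
  intervention machinery evaluates *given* schedules, it does not optimize
  them.
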