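---
title: "Bilinear chemotherapy models: simulation, controllability, and sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilinear chemotherapy models: simulation, controllability, and sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemoctrl)
```

## The model

Cell-cycle-specific chemotherapy models cluster the cycle phases
(G0/G1/S/G2/M) into $n$ compartments whose average cell counts $N(t)$ evolve
bilinearly in the state and the drug effect:

$$\frac{dN}{dt} = \bigl(A + s(c)\,B\bigr)\,N, \qquad N(0) = N_0,$$

where $A$ is the intrinsic inter-compartment flow/growth matrix
(1/time), $B$ couples the pharmacodynamic effect $s(c)$ into those flows,
and $c(t)$ is the plasma drug concentration governed by a one-compartment
pharmacokinetic equation with dose-dependent clearance:

$$\frac{dc}{dt} = -\bigl(k_1 + k_2\,u(t)\bigr)\,c + h\,u(t), \qquad c(0)=0.$$

Here $u(t) \ge 0$ is the dosing schedule (the control), $k_1 > 0$ the
first-order clearance, $h > 0$ the infusion gain, and $k_2$ a
dose-dependent clearance coefficient whose **sign is deliberately
unrestricted**: $k_2 > 0$ saturates the concentration, while $k_2 < 0$
models a drug whose effective elimination slows as dosing builds up, so
that $c$ can grow without bound.

The concentration-effect map is either the hyperbolic Emax curve or its
sigmoid Hill generalization,

$$s(c) = E_0 + \frac{E_{\max}\,c^{k}}{EC_{50}^{k} + c^{k}},$$

with $k = 1$ recovering the Emax model exactly (`drug_effect()` treats the
two as the same function in that case, and the package tests assert the
identity pointwise). Dosing performance over a therapy interval $[0, T]$
is scored by the L1-type objective

$$J = p\,N(T) + \int_0^T \bigl(q\,N(t) + b\,u(t)\bigr)\,dt,$$

whose terminal term penalizes the final tumor burden, whose running term
penalizes intermediate burden, and whose dose term is an indirect toxicity
proxy (the dose $u$, not the concentration $c$, is integrated — toxicity
to healthy tissue is represented only through the administered amount).

### Reference configuration and units

All quantities are in arbitrary units. `study_defaults()` returns the
one-compartment reference configuration used by the scenario registry:

| parameter | value | meaning |
|---|---|---|
| $E_0$ | 0 | baseline efficacy |
| $E_{\max}$ | 100 | maximum efficacy |
| $EC_{50}$ | 15 | half-max concentration |
| $k$ | 1 | Hill exponent (Emax model) |
| $k_1$ | 0.005 | first-order clearance |
| $k_2$ | 0.0004 | dose-dependent clearance |
| $h$ | 0.001 | infusion gain |
| $A$ | 0.001 | intrinsic growth (scalar) |
| $B$ | 0.001 | effect coupling (scalar) |
| $u(t)$ | $10\cos(0.1t) + 10$ | periodic administration |
| $p, q, b$ | 1 | objective weights |
| $T$ | 500 | therapy horizon |

Two deliberate modelling readings are worth flagging. First, the effect
$s$ is often described abstractly as mapping into $[0, 1]$, but the
reference parameterization uses $E_{\max} = 100$, so $s(c) \in [0, 100)$
feeds directly into $B$ without rescaling; we implement the concrete
parameterization and do not attempt to reconcile the two conventions.
Second, with $B > 0$ the "effect" accelerates compartment growth rather
than killing cells; the objective-vs-$k_2$ experiment inherits this sign
convention. Both choices follow the configuration as printed; users can
supply negative `b_matrix` entries for cytotoxic couplings.

The initial cell count is not part of the printed configuration; we
default to $N_0 = 1$ per compartment. Because the tumor equation is
linear in $N$, every trajectory (and the $N$-dependent part of $J$)
scales proportionally with $N_0$, so nothing qualitative depends on this
choice.

## Numerical choices

- **Integrator.** `simulate_chemo()` uses the adaptive explicit
  Runge-Kutta 4(5) pair (deSolve's `ode45`), `rtol = 1e-8`,
  `atol = 1e-10`. The system is non-stiff at the reference parameters.
  The *reporting grid* — by default unit spacing on $[0, 500]$ — defines
  the trajectory rows; solver steps are internal, and doubling the grid
  resolution changes reported values only at the solver-tolerance level.
- **Blow-up guard.** With sufficiently negative $k_2$ the concentration
  grows exponentially; any state exceeding $10^{12}$ in magnitude aborts
  the run with a diagnostic naming the divergent state.
- **Dose positivity** is enforced by validation on the reporting grid,
  not by clipping: a schedule that dips below zero is rejected outright.
- **Concentration clamp.** The solver may transiently evaluate
  $c = -\epsilon$ near zero; the effect function receives
  $\max(c, 0)$ so the Hill curve's domain constraint is never violated.
- **Quadrature.** The running cost integral uses the composite trapezoid
  rule on the reporting grid; composite Simpson is available as a
  cross-check (`rule = "simpson"`) and the two agree to within $10^{-5}$
  relative on reference trajectories. Objective additivity
  ($J = $ terminal $+$ running) is exact by construction.
- **Closed-form oracle.** `closed_form_lti()` evaluates the
  variation-of-constants solution
  $x(t) = e^{At}[x_0 + \int_0^t e^{-A\tau} B u(\tau)\,d\tau]$ with
  `Matrix::expm()` and a 96-node Gauss-Legendre rule, giving an
  independent near-machine-precision reference for linear
  specializations (e.g. the concentration equation when $k_2 = 0$).
- **Numerical rank.** `is_controllable()` uses singular values with the
  standard tolerance `max(dim) * eps * sigma_max`, overridable via
  `rank_tol`.
- **JSON round trip.** Parameter bundles serialize with 17 significant
  digits, so doubles survive a write/read cycle bit-exactly.

## Controllability

The Kalman criterion — an LTI system $\dot x = Ax + Bu$ is controllable
iff $[B \,|\, AB \,|\, \cdots \,|\, A^{n-1}B]$ has rank $n$ — applies to
*linear* systems only; the bilinear chemotherapy model is not LTI.
`linearize_chemo()` therefore provides a Jacobian linearization about a
reference state $(N^\ast, c^\ast)$ and dose $u^\ast$ as an explicitly
labelled approximation: conclusions drawn from its rank speak to the
linearized model near that operating point, not to the bilinear system
globally. At the reference configuration the linearization at the
constant-dosing fixed point is controllable (rank 2): the input reaches
$c$ directly and reaches $N$ through the PD coupling $s'(c^\ast) B N^\ast$.
Setting $B = 0$ severs that path and the rank test correctly reports
uncontrollability.

## The sensitivity study

`lhs_sample()` draws Latin hypercube samples: for each parameter the
$n$ draws occupy the $n$ equal-width strata of its range exactly once,
uniformly within strata, deterministically for a fixed seed. The default
ranges span an order of magnitude around the reference values
($k_1, h, A, B \in [0.001, 0.01]$, $k_2 \in [0, 0.01]$, Hill exponent
$\in [1, 5]$; continuous Hill draws are rounded to the nearest integer
because the exponent is integer-valued).

`sensitivity_envelope()` summarizes the family of output curves pointwise
by min, max, 5%/95% quantiles, mean and median. The 5%/95% choice for
the inner band is our own; nothing downstream depends on it, and the
pointwise ordering min $\le$ q05 $\le$ median $\le$ q95 $\le$ max is a
tested invariant. Individual draws that fail to integrate (possible under
extreme negative-$k_2$ user ranges; the default ranges produce none) are
excluded with a warning and counted, never fatal.

`rank_parameters()` scores each parameter one-at-a-time by the
time-integrated envelope width normalized by the time-integrated
baseline curve,
$$\mathrm{score} = \frac{\int_0^T (\max_i y_i(t) - \min_i y_i(t))\,dt}
  {\int_0^T y_{\mathrm{base}}(t)\,dt},$$
which mirrors the visual band-width comparison of envelope plots. No
particular summary statistic is canonical here; the integrated width is
the most direct quantification of "how wide the band is".

A structural point does most of the work in the concentration ranking:
the PK equation contains none of $A$, $B$, $E_0$, $E_{\max}$, $EC_{50}$
or the Hill exponent, so $c(t)$ is *functionally independent* of them and
their concentration scores are exactly zero — not merely small. The
package exploits this: concentration-output studies integrate the PK
subsystem alone (exact, since $c$ never feeds back from $N$), which also
makes the zero-score property hold to the bit. At the reference
configuration with 100 samples per parameter the scores computed by
`run_scenario("sensitivity_each")` rank $h > k_2 > k_1 \gg
\{k, A, B\} = 0$: the model is sensitive to the three PK parameters and
insensitive to the rest. For cell-count or objective outputs
(`output = "N"`, `"J"`) the full coupled system is integrated and $A$,
$B$ do matter; a test asserts their scores turn strictly positive there.

One-at-a-time ranking isolates each parameter's contribution; the joint
scenario (`sensitivity_joint`) varies $k_1$, $k_2$, $h$ together to show
their combined envelope. Default 100 samples: Monte-Carlo stability of
the scores at this size is about 10-20% relative (a tested property), and
each extra sample is one ODE solve.

## The scenario registry

`run_scenario()` reproduces five reference experiments from configuration
alone, writing CSV tables and a JSON summary whose parameters + seed
round-trip to identical outputs. Scenario assertions are *recorded*, not
raised, so a run always yields inspectable output:

- **baseline** — periodic dosing on $[0, 500]$; records the plateau
  diagnostic (sd of $c$ over the last fifth of the horizon relative to
  the first fifth) and the synchrony lag between concentration and dose
  fluctuations (the concentration trails the dose by about a quarter
  period, $\approx 14$ time units at $\omega = 0.1$).
- **sensitivity_each / sensitivity_joint** — the ranking and joint
  envelope described above.
- **objective_vs_k2** — $J$ along an ascending 25-point log-spaced
  $k_2$ grid on $[10^{-4}, 10^{-2}]$ (the grid is our choice; the upper
  bound matches the sensitivity range, and log spacing resolves the steep
  initial descent). $J$ decreases strictly along the grid: larger $k_2$
  lowers the saturated concentration, hence the effect, hence the
  $B$-driven growth and the running burden.
- **negative_k2** — flips $k_2$ to $-0.0004$; $c(t)$ abandons the
  saturating regime and grows, ending at $\approx 3.87$ versus
  $\approx 1.09$ for the positive-$k_2$ baseline.

### What the plateau and monotonicity checks do and do not show

Two scenario assertions quantify claims that are visually compelling on a
plot but literally false for the continuous dynamics, and both are
reported honestly as measured:

- With $k_2 > 0$ the concentration under periodic dosing converges not to
  a constant but to a *periodic steady state*: the forced linear
  time-varying PK equation retains a ripple of amplitude
  $\approx h\,\Delta u / \sqrt{(k_1 + k_2 \bar u)^2 + \omega^2} \approx
  0.05$ forever. On a figure spanning $0$-$1.2$ this ripple is invisible
  ("a plateau"), but the late/early sd ratio computed by the baseline
  scenario is $\approx 0.20$ at $T = 500$ and never falls below
  $\approx 0.14$ at any horizon, so the strict `plateau_detected`
  check (ratio $< 0.1$) is false for this model. The summary records
  both the boolean and the measured ratio.
- With $k_2 < 0$ the late-time growth rate $-(k_1 + k_2 u(t))$ still
  turns negative near every dose trough ($u \approx 0$ gives
  $dc/dt = -k_1 c < 0$), so $c$ dips by $\approx 0.5\%$ per time unit
  there and pointwise monotonicity fails at every horizon. The
  dose-cycle-averaged trend *is* monotone increasing, and the summary
  records both checks (`late_monotone_increase`, `late_trend_increasing`).

## What the generator emulates, and limitations

The scenario registry *is* the data-generating process: there is no
external data, and every analysis input (parameter draws, dose schedules,
time grids) is produced in code from the reference configuration. What
passing tests demonstrate is therefore internal consistency of the model
family — convergence to analytic fixed points, agreement with
closed-form linear solutions, exact structural independences — not
fidelity to any clinical system. Real tumor growth data would bring
measurement noise, inter-patient variability, nonlinear (e.g. Gompertz or
logistic) saturation, resistance evolution and delayed drug action, none
of which this bilinear family represents. The insensitivity of $c(t)$ to
the tumor-side parameters is itself a structural limitation of the model
class — the drug-cell interaction compartment has no influence on the
kinetics — rather than a biological finding.

Other limitations: multi-drug controls with distinct coupling matrices
are not implemented (single-drug specialization only); bolus/event-based
dosing is not among the schedule forms; controllability is assessed only
through the labelled linearization; and no optimization over schedules is
performed — the package evaluates $J$, it does not synthesize optimal
controls.

## Problem sizes

Defaults throughout were chosen as the sizes a study of this model family
actually needs: horizons of 500 time units at unit reporting spacing
(2000 for fixed-point convergence), 100 Latin hypercube samples per
parameter (600 PK solves for the full ranking), 25-point sweep grids, and
20-25 random instances per property-style matrix test.
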