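---
title: "Modelling addiction as a bistable craving/self-control system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling addiction as a bistable craving/self-control system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cravingdyn)
```

## The model and its assumptions

`cravingdyn` treats addictive behaviour that coexists with ordinary daily life
— habitual alcohol consumption is the guiding case — as a discrete-time
dynamical system with a weekly step, matching the weekly cycle of most
lifestyles. Two state variables evolve: craving `C`, the degree to which the
mind is absorbed by the deprivation of the behaviour, scaled to `[0, 1]`; and
the effect of self-control `S`, placed on the same scale so the two can
compete (and allowed to go negative under depletion). Their difference,
shifted by an external control parameter `E`, gives the addiction
vulnerability `V = min(1, max(0, C − S − E))`, and acting out is proportional
to it: `A = qV`, with `q` the maximal weekly consumption.

The weekly updates are

\[
\begin{aligned}
C_{t+1} &= C_t + b\,\min(1, 1 - C_t)\,A_t - d\,C_t,\\
S_{t+1} &= S_t + p\,\max(0, S^+ - S_t) - h\,C_t - k\,A_t.
\end{aligned}
\]

The craving equation is the only nonlinearity with consequences: the impact
of consumption on craving shrinks linearly as craving saturates, which is
what creates two coexisting attractors instead of unbounded growth. The
self-control equation embodies the finite-resource ("ego depletion") view:
restoration is proportional to the left-over capacity `S⁺ − S` with
resilience `p`, and both craving and the behaviour itself consume the
resource.

Key structural assumptions, inherited deliberately:

* the week is atomic — within-week (hourly) drinking episodes are not
  modelled, only their weekly total `A`;
* self-control **capacity** changes on a time scale of years and is treated
  as the constant ceiling `S⁺`; only its momentary *effect* `S` is dynamic;
* cues from unrelated sources arrive as one Poisson count `R ~ Poisson(λ)`
  per week, each adding `q/7` (one day's worth of maximal consumption) to
  `A`, capped at `q(1 − V)` so the weekly total never exceeds `q`.

## Parameters

| parameter | meaning | unit | default | rationale |
|---|---|---|---|---|
| `d` | craving unlearning rate | /week | 0.2 | decay of craving on the order of months |
| `q` | maximal weekly consumption | kg alcohol/week | 0.8 | ≈ 80 drinks/week, an extreme intake |
| `S⁺` | ceiling of the self-control effect | C-scale | 0.5 | capacity able to offset moderate craving |
| `b` | cue sensitivity | /(kg/week) | `2d/q` = 0.5 | half-maximal consumption leaves craving stationary at `C = 1/2` |
| `p` | resilience (restoration rate) | /week | `2d` = 0.4 | self-control must restore faster than craving decays |
| `h` | depletion per unit craving | /week | `pS⁺` = 0.2 | the two depletion terms are of equal strength and |
| `k` | depletion per unit consumption | /(kg/week)/week | `pS⁺/q` = 0.25 | together match the maximal restoring force: `h/2 = kq/2 = pS⁺/2` |

`calibrate_params()` *derives* `b`, `p`, `h`, `k` from `d`, `q`, `S⁺` through
these identities at run time, so the calibration itself is testable. Units
are documentation only; no conversions are ever performed. All state is
dimensionless except `A` and `q`.

The constructor rejects parameter sets with `b·q ≥ 1`. Under `b·q < 1` and
`d < 1`, craving started in `[0, 1]` remains there — at the upper end
`C' - 1 = (C - 1)(1 - bA) - dC \le 0`, at the lower end `C' \ge (1 - d)C \ge 0`
— so the simulator applies **no clamping** to `C` or `S`. Silent clamping
would mask parameter-regime errors; boundedness is a theorem here, not a
safety net, and the property tests exercise it on random parameter draws.

## Update order within a week

All right-hand sides are written at time `t`, and the implementation honours
that literally: week `t` first draws the cue count `R_t` and forms
`(A_t, V_t)` from the current `(C_t, S_t, E_t)`, then updates `C` and `S`
**synchronously** from week-`t` values, then advances any driver schedules.
Whether the original spreadsheet formulation stepped the two states
synchronously or sequentially is not decidable from the equations alone; the
fixed points are identical either way, and the synchronous choice is the one
the notation states. Sequential variants were examined while validating the
stochastic regimes and shift transient volatility only modestly (see
*Limitations*).

## Equilibria, stability, and the branch diagram

With `λ = 0` the map is piecewise linear-quadratic with three regimes, each
solvable in closed form:

* **abstinent** (`V` clamped at 0): `(0, S⁺)`, valid iff `E ≥ −S⁺`;
* **saturated** (`V` clamped at 1): `C^* = bq/(d + bq)`,
  `S^* = S⁺ − (hC^* + kq)/p`, valid iff `C^* − S^* − E ≥ 1` — within the
  regime the coordinates are independent of `E`;
* **interior**: the stationary `S`-balance is linear in `S` given `C`;
  substitution into the stationary `C`-balance leaves a quadratic in `C`
  (for the defaults, `3C² − (3.5 + 2E)C + (1 + 2E) = 0`), whose real roots
  are kept only when `0 < C − S − E < 1` holds.

Stability comes from the 2×2 Jacobian assembled with the regime-specific
branch of each `min`/`max`; an equilibrium is stable iff both eigenvalue
moduli are below `1 − 10⁻⁹`. Numerical choices worth recording:

* **Regime boundaries.** A fixed point sitting exactly on a clamp boundary
  (e.g. the saturated state at `E = 0`, where `C^* − S^* − E = 1`; or the
  abstinent state, whose `S` sits on the restoration kink at `S⁺`) is
  assigned to the clamped regime, flagged `boundary = TRUE`, and linearized
  with the branch from which the dynamics approach (restoration active,
  consumption clamped). The map is continuous but not differentiable there,
  so the flag warns that the one-sided linearizations differ.
* **Deduplication.** An interior quadratic root landing on a clamp boundary
  coincides with the clamped regime's fixed point and is reported once,
  under the clamped label; coincidence is declared below `10⁻⁹` in both
  coordinates.
* **Degeneracy.** The interior reduction divides by `kq − p`; at `kq = p` it
  signals an error and the numeric oracle (`brute_force_equilibria()`, a
  dense grid of Newton starts with finite-difference Jacobians on the step
  residual) is the fallback. The defaults give `kq − p = −0.2`, safely away.
  The oracle searches the invariant region `S ≤ S⁺` only: restoration never
  lifts `S` above the ceiling and depletion only lowers it, so points above
  `S⁺` with `C = A = 0` are stationary but unreachable initialization
  artifacts, not dynamics.
* **Fold refinement.** `sweep_branches()` grids `E`, and where the
  equilibrium count changes refines the location by bisection on the
  interior quadratic's discriminant (closed form, exact) — for the defaults
  the interior pair folds at `E = (10 − \sqrt{96})/8 ≈ 0.02526`. Count
  changes without a discriminant sign change (the abstinent branch endpoint
  at `E = −S⁺`, where the unstable branch merges into `C = 0`) are refined
  by bisection on the count itself. The default window `[−0.6, 0.35]`
  slightly exceeds the bistable range so both branch endpoints are visible.

## Scenarios

**Onset under lifestyle change.** Starting abstinent in a protective
environment (`E₀ = 1`) with moderate cues (`λ₀ = 0.5`), `E` drifts down and
`λ` up to stationary end values that decide the outcome. The drift rates are
not structurally determined; the package defaults to `dE = dλ = 0.01`/week
with `E_end = 0`, `λ_end = 1`, chosen once so that the drivers traverse the
bistable window over roughly three years. All are configurable.

**Stationary relapse regime.** Fixed `E = 0.1525`, `λ = 1` over 520 weeks
(about ten years). This `E` sits just past the deterministic fold, so the
addicted state exists only as a stochastic, cue-sustained phase — its
vulnerability fluctuates below saturation, which is what makes spontaneous
recovery possible at all (at `V = 1` the cue cap removes all noise). The
default initial state is abstinent `(0, S⁺)`; an addicted start
(`C0 = 2/3, S0 = −1/3`) shows the recovery side of the alternation.

**Therapeutic intervention.** The protocol fixes the post-treatment
lifestyle first (`S⁺ = 0.5`, `λ = 0.5`, `E = 0`), then doubles the restoring
force via `p = 0.8` and halves cue exposure to `λ = 0.25` for 7 weeks.
Design choices:

* the initial state is the **deterministic** addicted equilibrium of the
  baseline environment rather than a stochastic burn-in — reproducible, and
  the baseline addicted state carries no cue noise anyway (`V = 1`);
* treatment occupies weeks 0–6 inclusive; evaluation is the single week
  `t = 100` counted from treatment start;
* success is strict: `V(100) < 0.5`; exact equality (probability ~0) counts
  as failure, the conservative tie-break;
* cues stay on throughout treatment (the treated `λ = 0.25` implies cue
  exposure persists, merely reduced);
* replicates draw their seeds once from the master seed, so replicate `r`
  is reproducible in isolation; the success rate is reported with a 95%
  Wilson score interval (well-behaved at small `n` and extreme rates).

## What the stochastic generator does and does not emulate

The Poisson cue process reproduces week-to-week fluctuations in exposure
from many independent sources, including the occasional cue pile-up that can
tip a marginal state across a basin boundary. It does not model bursty or
clustered cues, cue covariates (weekends, seasons), individual differences,
measurement error, or any change in self-control capacity `S⁺`. Passing
tests therefore demonstrate the internal consistency of the model and its
analysis, not fidelity to empirical drinking trajectories.

## Problem sizes

The test suite works at the scale the analyses need rather than the scale a
study would use: Monte Carlo batches of 50–2,000 interventions (101 weeks
each), stationary runs of 520–10,000 weeks, a branch sweep of 191 grid
points, and 200 random parameter draws for the solver-vs-oracle completeness
property. The acceptance script reports the intervention batch at `n = 50`
and logs an `n = 2000` estimate with its confidence interval.

## Limitations

* Under the calibrated defaults the cue noise produced by one Poisson count
  per week at `λ ≤ 1` is weak relative to the basin geometry: upward
  (relapse-into-addiction) transitions from the abstinent side are rare
  events. In the stationary regime at `E = 0.1525, λ = 1` the cue-sustained
  addicted phase fluctuates around `V ≈ 0.8` and spontaneous recovery is
  common from an addicted start, but full two-way alternation within a
  ten-year window occurs only occasionally, and the intervention success
  rate computed by the acceptance script is ≈ 93% rather than the ≈ 70%
  sometimes associated with this protocol. Both quantities are extremely
  sensitive to the post-treatment cue pressure (dropping from ≈ 95% at
  `λ = 0.5` to ≈ 5% at `λ = 1`), so modest differences in how cue forcing
  is realized move them strongly; the package reports what the equations as
  stated produce.
* The fold location and branch structure are exact only for the
  deterministic skeleton; stochastic "effective" bifurcations shift with
  `λ`.
* `E` aggregates all environmental influence into one number on the craving
  scale; it has no mechanistic decomposition here.
* The equilibrium solver covers the map's three regimes under `b·q < 1` and
  `kq ≠ p`; outside that envelope only the numeric oracle applies.
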