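---
title: "Drafting, pacing and the energetics of a sub-2-hour marathon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drafting, pacing and the energetics of a sub-2-hour marathon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacedraft)
library(dplyr)
```

## The question

Elite marathon pacing is, energetically, a drafting problem. At world-record
pace (about 5.86 m/s) a runner spends roughly 1.2 kW of mechanical power, of
which only some 30 W — around 3% — goes into pushing air aside. That share
sounds negligible until one notices how cheap marginal speed is in this
regime: because the cost of running per metre is nearly flat in speed,
reallocating a few tens of kilojoules of a ~8.5 MJ race budget buys seconds
to minutes of finish time. Shielding the runner behind pacers is the only
lever that changes the aerodynamic share without asking for more energy.

`pacedraft` implements the full accounting chain for this argument: a
mechanical running-power model, quadratic drag-versus-speed curves per
drafting formation and position, per-runner energy ledgers computed from
actual race split tables, and a three-phase race-time optimizer that asks
how fast the same runners could have covered the marathon had they used the
most aerodynamically effective formations — under the strict rule that
nobody may spend more energy than they demonstrably spent in the real race.

## The power model

Total mechanical power is mass times speed times the cost of running
$C_r$ (J kg^-1^ m^-1^), measured on elite Kenyan marathon runners on a
track:

$$W_{tot}(v) = m\,v\,(0.018\,v^2 + 3.2833).$$

Because track measurements include the work done against air resistance,
the aerodynamic component must be split back out before a different
formation can be priced. The drag on an unshielded runner is carried as a
quadratic fitted through CFD-style samples at four speeds (5.238, 5.475,
5.713, 5.950 m/s — the extremes observed across the analysed races with
the interval divided into three equal parts):

$$F_D(v) = 0.493\,v^2 - 3.256\,v + 7.878 \;\text{N},$$

giving 5.73 N at target pace and, via $W_a = F_D\,v$, the decomposition
$W_{na}(v) = W_{tot}(v) - W_a^{solo}(v)$. A runner in formation then costs
$W_{na}(v) + v\,F_D^{(f,p)}(v)$ with the drag curve of his formation $f$
and position $p$. The package verifies the decomposition closes to machine
precision, that drafting never increases modelled power, and that mass
scales total power exactly linearly.

```{r power}
p <- power_model_params() # 52 kg, the main runner's listed mass
c(total = total_power_tam(5.86, p),
  aero = aero_power(p$solo_drag_curve, 5.86),
  nonaero = nonaero_power(5.86, p))
```

Two older mass-specific power models (a force-platform power law and an
internal-plus-external work model) are included for comparison through
`compare_power_models()`. The comparison needs a calorie-to-joule
convention that published comparisons leave unstated; the package defaults
to the thermochemical calorie (4.184 J) and makes the factor an argument.
With that convention the two models disagree by a few percent at the top
of the racing speed range and by substantially more at its bottom, so the
function *reports* the maximum relative difference and where it occurs
rather than asserting any particular figure.

## The drag-curve catalog

Formations are labelled `SOLO` and `F1`–`F12` (one to six pacers; 1.2 m
longitudinal gaps). What the analysis needs from aerodynamics is exactly
one quadratic per (formation, position). `fit_drag_curve()` recovers such
a quadratic from sampled drag values by least squares — exactly, when the
samples are consistent with a single quadratic — and `build_catalog()`
assembles keyed collections from coefficients or samples, rejecting
duplicates, missing solo references and curves that go non-positive inside
the 5–6 m/s evaluation window.

The shipped `default_catalog()` is anchored to drag reductions quoted at
target pace for the main runner: 19% behind one laterally offset pacer
(F1), 42% behind two or three pacers (F2/F3), 54% directly behind one
pacer (F4), 62% with pacers fore and aft (F12), 74% for the five-pacer
inverted arrow (F11). A single-speed reduction is extended to the whole
window by scaling the solo polynomial by $(1-r)$ — the simplest
speed-consistent extension, flagged in every entry's provenance and
overridable by fitted coefficients whenever a full coefficient table is
available. Pacer positions are synthetic defaults (lead pacers at 0.97 of
solo drag, reflecting the small upstream benefit of a trailing body; the
sheltered rear position of F12 at 0.45). Two facts justify shipping
synthetic pacer curves: the optimized race times turn out to be almost
insensitive to them, because a pacer's budget (earned in the actual race)
and his spending rate (in the projected race) move together when his curve
changes; and every acceptance-grade result is reported with provenance so
the substitution stays visible.

Extrapolation outside a curve's fitted range warns rather than fails — the
optimizer's 5–6 m/s box sits almost entirely inside the fitted 5.238–5.950
range, and the quadratic form is not trusted far beyond it.

## Energy accounting of the actual races

`parse_splits()` converts a cumulative split table (one row per formation
phase) into per-phase durations, distances and speeds, cross-checking any
printed speed column to 0.002 m/s. The shipped transcriptions of the 2018
and 2022 Berlin marathons reproduce the printed per-phase speeds to three
decimals (the printed values are truncated, not rounded, which is why the
parser's tolerance is not zero).

```{r splits}
parse_splits(berlin_splits(2022))
```

`race_energy_ledger()` prices each runner's appearance in each phase
(exposure follows the dropout order implied by the shrinking formations;
positions are config-overridable) and `budgets_from_actual_race()` freezes
the totals as the conserved quantities of the optimization.

One calibration note. The published per-runner race energies for these
races exceed what the power model yields on the printed splits with 52 kg
runners by a near-uniform ~8% — consistent with an unstated mass-like
rescaling (pacer masses were never published). The package therefore checks
*orderings and ratios* against the published energy tables and recomputes
budgets self-consistently under its own model. Self-consistency also makes
the projected race times nearly invariant to any uniform rescaling of
power: a runner whose budget and spending rate are both 8% higher drops out
at the same moment.

## The three-phase optimization

The projected race follows the strategy that the drag results single out
as best with two pacers: start in F12 (strongest pacer leading at P1,
weakest trailing at P2) at speed $v_1$ until the weak pacer's budget is
exhausted, switch to F4 (remaining pacer ahead) at $v_2$ until he too is
spent, finish solo at $v_3$. Phase times follow from budgets and
instantaneous powers,

$$t_1 = E_{P2} / P_{P2}(v_1), \qquad t_2 = E_{P1}'/P_{P1}(v_2), \qquad
  t_3 = (42195 - v_1 t_1 - v_2 t_2)/v_3,$$

and the optimizer minimises $t_1+t_2+t_3$ over $v_1,v_2,v_3 \in [5,6]$
m/s subject to the main runner's energy-conservation equality. The
identity of the limiting pacer is decided by the smaller budget-to-power
ratio at the phase-1 speed, which generalises "the weakest pacer" to
rosters with unequal masses or curves; the catalog key pricing his phase-1
power defaults to (F12, P2) and is configurable, since the trailing
position of F12 is aerodynamically the natural reading.

Numerically, the pacer-exhaustion equalities hold by construction, so the
search space is really the $(v_1, v_2)$ box: for each candidate pair the
solo speed $v_3$ is obtained by root-finding on the main runner's energy
residual, which is strictly decreasing in $v_3$ (running the remainder
faster costs more). Where the equality cannot hold inside the bounds the
objective is penalised in proportion to the violation, keeping the search
smooth. The refinement is bounded quasi-Newton from 8 Latin-hypercube
starts under a fixed seed, making results deterministic; tests hold the
optimizer to within 0.5 s of an independent 0.02 m/s brute-force grid over
twenty generated scenarios. Totals are reported raw and rounded up to the
next whole second, the race-clock convention used for finish times.

Degenerate inputs are handled explicitly: zero pacer budgets collapse to a
pure solo race; pacers strong enough to outlast the finish line get their
phases truncated there and the outcome flagged, since the three-phase
strategy is then ill-posed. The equality constraint itself is a modelling
choice with a sharp edge — inflate the main runner's budget enough and no
in-bounds $v_3$ can burn it, so the equality becomes infeasible rather
than faster. `strategy_config(energy_constraint = "inequality")` provides
the spend-at-most variant for such sensitivity runs; at a binding budget
the two coincide, and monotonicity of optimal time in any budget is a
property of the inequality variant.

```{r optimize}
budgets <- budgets_from_actual_race(
  parse_splits(berlin_splits(2022)),
  berlin_roster(2022), berlin_exposure(2022)
)
opt <- optimize_strategy(budgets)
glance(opt)
```

Both Berlin scenarios optimize to sub-two-hour totals with a positive
split ($v_1 \ge v_2 \ge v_3$, phase-3 speed about 4% below the paced
phases): starting fast while shielded and slowing once alone beats the
popular negative-split intuition whenever two pacers are available for a
substantial part of the race.

### Sensitivity, and what the totals can and cannot pin down

The flip side of cheap marginal speed is that optimized finish times are
extremely sensitive to small energy-accounting differences: near the
optimum, one second of total time corresponds to only a few hundred joules
of the main runner's budget, i.e. parts in $10^4$. Published drag
reductions quoted to two figures therefore determine the optimized totals
only to within several seconds; reproducing a specific published total to
the second requires the underlying fitted drag coefficients for every
position, which the default catalog deliberately does not pretend to have.
The qualitative findings — sub-two-hour feasibility, positive splitting,
the ~4% phase-3 deficit, the ordering of the two races' improvements —
are robust to these choices, and the package asserts those; the shipped
analyses compute improvements of 114 s (2018) and 88 s (2022) over the
actual finishes under the default catalog.

### Cooperative drafting

`cooperative_variant()` re-optimises with phase 1 split into two equal
halves in which the pacers exchange the front and rear positions of F12,
so each spends at the mean of the two positional powers. Sharing the drag
burden keeps the weaker pacer in the race slightly longer; the re-optimised
saving is on the order of one second for both races (exactly zero when the
two positions have identical curves, which tests assert). The package
implements only this single half-split exchange: rotating pacer schedules
violate record rules and are out of scope.

## The synthetic-data generator

`generate_catalog()`, `generate_race_fixture()` and `generate_scenario()`
produce every input the pipeline consumes, deterministically under a seed.
The generator emulates the *statistical structure* the analysis assumes:
drag samples that are quadratic in speed (with optional Gaussian noise
standing in for CFD fit residuals — never noise on the power-model
constants, which the analysis treats as exact), main-runner reductions
drawn from the 0.19–0.74 range the studied formations span, races whose
formations shrink as pacers drop out, speeds in 5.2–6.0 m/s, cumulative
distance closing exactly at 42 195 m. Monte-Carlo tests check that noisy
fits are unbiased with the spread predicted by closed-form least-squares
covariance.

What the generator does not emulate — and hence what passing property
tests cannot certify about real races — is everything the model abstracts
away: course curvature and elevation, wind, formation-change transients,
hydration stops, fatigue beyond a fixed energy budget, and any
speed-dependence of drag reductions beyond constant-ratio scaling.

## Choices fixed at genuinely open points

* **Body mass 52 kg for every runner.** The cost-of-running constants are
  scaled to the main runner's listed mass and no pacer masses were
  published; mass is exposed as the natural knob (`berlin_roster(year,
  mass_kg = )`).
* **Thermochemical calorie** for the inter-model power comparison,
  configurable, with the result reported rather than asserted.
* **Reductions anchored at 5.86 m/s.** Some quoted reductions are stated
  at 5.83 m/s; under constant-ratio scaling the anchoring speed is
  immaterial, which is one more reason that scaling is the right default.
* **Limiting-pacer curve key (F12, P2)**, configurable via
  `strategy_config(limiting_key = )`.
* **Self-consistent budgets**, never published absolute energies, feed the
  optimizer (see the calibration note above).
* **Equality energy constraint by default**, inequality behind a flag.

## Problem sizes

The shipped analyses are small by construction — three or four phases,
three runners, a dozen curve entries — so the full pipeline (two races,
baseline and cooperative optima) runs in about a second. Property tests
use twenty seeded synthetic scenarios against the 0.02 m/s grid oracle and
one hundred Monte-Carlo replicates for the fit-covariance check, sizes
chosen to make the statistical assertions stable under any seed.
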